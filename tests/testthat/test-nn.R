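# Finite-difference validation of every hand-written layer gradient.

tn <- gmic3d:::tensor_new
loss_of <- function(out, R) sum(out$mat * R)

test_that("convolution matches a direct sliding-window computation", {
  set.seed(1)
  h <- 6L; w <- 5L; n <- 2L; cin <- 3L; cout <- 2L
  x <- tn(matrix(rnorm(n * h * w * cin), n * h * w, cin), h, w, n)
  W <- gmic3d:::init_conv_w(3L, 3L, cin, cout)
  b <- rnorm(cout)
  fw <- gmic3d:::conv2d_forward(x, W, b, stride = 1L, pad = 1L)
  # direct computation at a few positions
  xa <- array(x$mat, c(h, w, n, cin))
  # W rows are (cin fastest, then kernel row di, then kernel column dj)
  Wk <- array(W, c(cin, 3, 3, cout))
  for (probe in list(c(1, 1, 1, 1), c(3, 4, 2, 2), c(6, 5, 1, 2))) {
    i <- probe[1]; j <- probe[2]; s <- probe[3]; co <- probe[4]
    acc <- b[co]
    for (dj in -1:1) for (di in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        acc <- acc + sum(xa[ii, jj, s, ] * Wk[, di + 2, dj + 2, co])
      }
    }
    got <- array(fw$out$mat, c(h, w, n, cout))[i, j, s, co]
    expect_equal(got, acc, tolerance = 1e-12)
  }
})

test_that("convolution gradients match finite differences", {
  set.seed(2)
  h <- 5L; w <- 4L; n <- 2L; cin <- 2L; cout <- 3L
  x0 <- matrix(rnorm(n * h * w * cin), n * h * w, cin)
  W <- gmic3d:::init_conv_w(3L, 3L, cin, cout)
  b <- rnorm(cout)
  run <- function(xm, Wm, bm) {
    attr(Wm, "kernel") <- c(3L, 3L)
    gmic3d:::conv2d_forward(tn(xm, h, w, n), Wm, bm, stride = 2L, pad = 1L)
  }
  fw <- run(x0, W, b)
  R <- matrix(rnorm(length(fw$out$mat)), nrow(fw$out$mat))
  bw <- gmic3d:::conv2d_backward(tn(R, fw$out$h, fw$out$w, n), fw$cache)
  gx <- fd_grad(function(v) loss_of(run(matrix(v, nrow(x0)), W, b)$out, R), as.vector(x0))
  gW <- fd_grad(function(v) loss_of(run(x0, matrix(v, nrow(W)), b)$out, R), as.vector(W))
  gb <- fd_grad(function(v) loss_of(run(x0, W, v)$out, R), b)
  expect_lt(rel_err(as.vector(bw$dx$mat), gx), 1e-6)
  expect_lt(rel_err(as.vector(bw$dW), gW), 1e-6)
  expect_lt(rel_err(bw$db, gb), 1e-6)
})

test_that("group norm is per-sample and its gradients check out", {
  set.seed(3)
  h <- 3L; w <- 3L; n <- 2L; C <- 8L
  x0 <- matrix(rnorm(n * h * w * C), n * h * w, C)
  gamma <- runif(C, 0.5, 1.5); beta <- rnorm(C)
  fw <- gmic3d:::group_norm_forward(tn(x0, h, w, n), gamma, beta)
  # per-sample: changing sample 2 leaves sample 1's output untouched
  x1 <- x0; x1[(h * w + 1):(2 * h * w), ] <- rnorm(h * w * C)
  fw1 <- gmic3d:::group_norm_forward(tn(x1, h, w, n), gamma, beta)
  expect_identical(fw$out$mat[1:(h * w), ], fw1$out$mat[1:(h * w), ])

  R <- matrix(rnorm(length(x0)), nrow(x0))
  bw <- gmic3d:::group_norm_backward(tn(R, h, w, n), fw$cache)
  f <- function(v) loss_of(gmic3d:::group_norm_forward(
    tn(matrix(v, nrow(x0)), h, w, n), gamma, beta)$out, R)
  expect_lt(rel_err(as.vector(bw$dx$mat), fd_grad(f, as.vector(x0), 1e-4)), 1e-5)
  fg <- function(v) loss_of(gmic3d:::group_norm_forward(
    tn(x0, h, w, n), v, beta)$out, R)
  expect_lt(rel_err(bw$dgamma, fd_grad(fg, gamma)), 1e-6)
  fb <- function(v) loss_of(gmic3d:::group_norm_forward(
    tn(x0, h, w, n), gamma, v)$out, R)
  expect_lt(rel_err(bw$dbeta, fd_grad(fb, beta)), 1e-6)
})

test_that("batch norm training gradients and running statistics", {
  set.seed(4)
  h <- 2L; w <- 2L; n <- 3L; C <- 4L
  x0 <- matrix(rnorm(n * h * w * C), n * h * w, C)
  gamma <- runif(C, 0.5, 1.5); beta <- rnorm(C)
  run0 <- list(mean = rep(0, C), var = rep(1, C))
  fw <- gmic3d:::batch_norm_forward(tn(x0, h, w, n), gamma, beta, run0, TRUE)
  mu <- colMeans(x0)
  expect_equal(fw$running$mean, 0.9 * 0 + 0.1 * mu)
  R <- matrix(rnorm(length(x0)), nrow(x0))
  bw <- gmic3d:::batch_norm_backward(tn(R, h, w, n), fw$cache)
  f <- function(v) loss_of(gmic3d:::batch_norm_forward(
    tn(matrix(v, nrow(x0)), h, w, n), gamma, beta, run0, TRUE)$out, R)
  expect_lt(rel_err(as.vector(bw$dx$mat), fd_grad(f, as.vector(x0), 1e-4)), 1e-4)
  # eval mode uses the running stats and is elementwise in x
  fe <- gmic3d:::batch_norm_forward(tn(x0, h, w, n), gamma, beta, fw$running, FALSE)
  be <- gmic3d:::batch_norm_backward(tn(R, h, w, n), fe$cache)
  expect_equal(as.vector(be$dx$mat),
               as.vector(gmic3d:::row_mul(gmic3d:::row_mul(R, gamma),
                                          1 / sqrt(fw$running$var + 1e-5))))
})

test_that("pooling layers and their gradients", {
  set.seed(5)
  h <- 6L; w <- 6L; n <- 2L; C <- 3L
  x0 <- matrix(rnorm(n * h * w * C), n * h * w, C)
  fw <- gmic3d:::avg_pool_forward(tn(x0, h, w, n), 3L)
  xa <- array(x0, c(h, w, n, C))
  expect_equal(array(fw$out$mat, c(2, 2, n, C))[1, 2, 2, 3],
               mean(xa[1:3, 4:6, 2, 3]))
  R <- matrix(rnorm(length(fw$out$mat)), nrow(fw$out$mat))
  bw <- gmic3d:::avg_pool_backward(tn(R, 2L, 2L, n), fw$cache)
  g <- fd_grad(function(v) loss_of(gmic3d:::avg_pool_forward(
    tn(matrix(v, nrow(x0)), h, w, n), 3L)$out, R), as.vector(x0))
  expect_lt(rel_err(as.vector(bw$mat), g), 1e-6)

  gp <- gmic3d:::gap_forward(tn(x0, h, w, n))
  expect_equal(gp$out[2, 3], mean(xa[, , 2, 3]))
  Rg <- matrix(rnorm(n * C), n, C)
  bg <- gmic3d:::gap_backward(Rg, gp$cache)
  gg <- fd_grad(function(v) sum(gmic3d:::gap_forward(
    tn(matrix(v, nrow(x0)), h, w, n))$out * Rg), as.vector(x0))
  expect_lt(rel_err(as.vector(bg$mat), gg), 1e-6)
})

test_that("attention backward matches finite differences", {
  set.seed(6)
  K <- 4L; S <- 7L; L <- 5L
  feats <- matrix(rnorm(K * S), K, S)
  P <- list(att_V = matrix(rnorm(L * S, sd = 0.3), L, S),
            att_U = matrix(rnorm(L * S, sd = 0.3), L, S),
            att_w = matrix(rnorm(L), L, 1))
  R <- rnorm(K)
  f_of <- function(P2, feats2) {
    sum(gmic3d:::attention_forward(feats2, P2)$alpha * R)
  }
  fw <- gmic3d:::attention_forward(feats, P)
  bw <- gmic3d:::attention_backward(R, fw$cache, P)
  for (nm in c("att_V", "att_U", "att_w")) {
    g <- fd_grad(function(v) {
      P2 <- P; P2[[nm]] <- matrix(v, nrow(P[[nm]])); f_of(P2, feats)
    }, as.vector(P[[nm]]))
    expect_lt(rel_err(as.vector(bw[[nm]]), g), 1e-6)
  }
  gf <- fd_grad(function(v) f_of(P, matrix(v, K)), as.vector(feats))
  expect_lt(rel_err(as.vector(bw$dfeats), gf), 1e-6)
})

test_that("adam takes bias-corrected steps and accumulation adds grads", {
  p <- list(a = matrix(1, 2, 2))
  st <- gmic3d:::adam_init(p)
  g <- list(a = matrix(2, 2, 2))
  up <- gmic3d:::adam_step(p, g, st, lr = 0.1)
  # first step moves by ~lr against the gradient sign
  expect_equal(as.vector(up$params$a), rep(1 - 0.1 * (2 / (2 + 1e-8)), 4))
  expect_identical(up$state$t, 1L)
  acc <- gmic3d:::grads_add(NULL, list(a = 1, b = 2))
  acc <- gmic3d:::grads_add(acc, list(a = 3, b = 4))
  expect_equal(acc, list(a = 4, b = 6))
})
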
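# Minimal neural-network primitives on base R matrices.
#
# Activations travel as "tensors": list(mat, h, w, n) where `mat` is an
# (n*h*w) x C matrix. Rows are ordered sample-major, and within a sample
# pixels are in column-major (row index fastest) order of the (h, w) plane,
# matching how R linearizes a matrix. All layers are pure functions that
# return the output plus a cache consumed by the matching *_backward().

tensor_new <- function(mat, h, w, n) {
  stopifnot(nrow(mat) == n * h * w)
  list(mat = mat, h = h, w = w, n = n)
}

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# add a length-C row vector to every row of an (N, C) matrix / multiply by it
row_add <- function(y, b) y + rep(b, each = nrow(y))
row_mul <- function(y, g) y * rep(g, each = nrow(y))

# ---- convolution ------------------------------------------------------------

conv_out_dim <- function(h, k, stride, pad) (h + 2L * pad - k) %/% stride + 1L

# Gather indices into the zero-padded plane for each kernel offset.
# Offsets are enumerated column-major (di fastest), matching the row layout
# of the weight matrix (kh*kw blocks of Cin columns in the im2col matrix).
# Geometries are memoized per (h, w, n, kh, kw, stride, pad).
.geom_cache <- new.env(parent = emptyenv())

conv_geometry_cached <- function(h, w, n, kh, kw, stride, pad) {
  key <- paste(h, w, n, kh, kw, stride, pad, sep = "_")
  g <- .geom_cache[[key]]
  if (is.null(g)) {
    g <- conv_geometry(h, w, n, kh, kw, stride, pad)
    .geom_cache[[key]] <- g
  }
  g
}

conv_geometry <- function(h, w, n, kh, kw, stride, pad) {
  oh <- conv_out_dim(h, kh, stride, pad)
  ow <- conv_out_dim(w, kw, stride, pad)
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  oi <- (seq_len(oh) - 1L) * stride + 1L     # padded row of kernel origin
  oj <- (seq_len(ow) - 1L) * stride + 1L
  samp_off <- (seq_len(n) - 1L) * hp * wp
  ridx <- vector("list", kh * kw)
  k <- 1L
  for (dj in 0:(kw - 1L)) {
    for (di in 0:(kh - 1L)) {
      plin <- outer(oi + di, (oj + dj - 1L) * hp, "+")   # oh x ow, col-major
      ridx[[k]] <- as.vector(outer(as.vector(plin), samp_off, "+"))
      k <- k + 1L
    }
  }
  # rows of the padded matrix that hold original (unpadded) pixels
  plin0 <- outer(seq_len(h) + pad, (seq_len(w) + pad - 1L) * hp, "+")
  inner <- as.vector(outer(as.vector(plin0), samp_off, "+"))
  list(oh = oh, ow = ow, hp = hp, wp = wp, ridx = ridx, inner = inner)
}

pad_tensor <- function(x, geom) {
  xp <- matrix(0, x$n * geom$hp * geom$wp, ncol(x$mat))
  xp[geom$inner, ] <- x$mat
  xp
}

# W: (kh*kw*Cin, Cout) matrix with attr "kernel" = c(kh, kw); b: length Cout
conv2d_forward <- function(x, W, b, stride = 1L, pad = 0L) {
  kk <- attr(W, "kernel")
  cin <- nrow(W) / (kk[1] * kk[2])
  geom <- conv_geometry_cached(x$h, x$w, x$n, kk[1], kk[2], stride, pad)
  xp <- pad_tensor(x, geom)
  col <- matrix(0, x$n * geom$oh * geom$ow, nrow(W))
  for (k in seq_along(geom$ridx)) {
    col[, ((k - 1L) * cin + 1L):(k * cin)] <- xp[geom$ridx[[k]], , drop = FALSE]
  }
  y <- row_add(col %*% W, b)
  out <- tensor_new(y, geom$oh, geom$ow, x$n)
  list(out = out, cache = list(col = col, geom = geom, cin = cin,
                               W = W, n = x$n, h = x$h, w = x$w))
}

conv2d_backward <- function(dout, cache, need_dx = TRUE) {
  W <- cache$W
  geom <- cache$geom
  cin <- cache$cin
  dW <- crossprod(cache$col, dout$mat)
  attr(dW, "kernel") <- attr(W, "kernel")
  db <- colSums(dout$mat)
  dx <- NULL
  if (need_dx) {
    dcol <- dout$mat %*% t(W)
    dxp <- matrix(0, cache$n * geom$hp * geom$wp, cin)
    for (k in seq_along(geom$ridx)) {
      idx <- geom$ridx[[k]]
      dxp[idx, ] <- dxp[idx, ] + dcol[, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    }
    dx <- tensor_new(dxp[geom$inner, , drop = FALSE], cache$h, cache$w, cache$n)
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- normalization ----------------------------------------------------------

# Group normalization: statistics per (sample, channel-group), no batch
# dependence. `groups` must divide the channel count.
group_norm_forward <- function(x, gamma, beta, groups = 8L, eps = 1e-5) {
  C <- ncol(x$mat)
  stopifnot(C %% groups == 0L)
  cpg <- C %/% groups
  grp <- rep(seq_len(groups), each = cpg)
  sidx <- rep(seq_len(x$n), each = x$h * x$w)
  m <- x$h * x$w * cpg
  gs <- rowsum(x$mat, sidx, reorder = FALSE)            # n x C
  gs2 <- rowsum(x$mat * x$mat, sidx, reorder = FALSE)
  Gind <- outer(grp, seq_len(groups), "==") + 0          # C x groups
  mu <- (gs %*% Gind) / m                                # n x groups
  ex2 <- (gs2 %*% Gind) / m
  invstd <- 1 / sqrt(pmax(ex2 - mu * mu, 0) + eps)
  muf <- mu[sidx, grp, drop = FALSE]
  isf <- invstd[sidx, grp, drop = FALSE]
  xhat <- (x$mat - muf) * isf
  y <- row_add(row_mul(xhat, gamma), beta)
  list(out = tensor_new(y, x$h, x$w, x$n),
       cache = list(xhat = xhat, isf = isf, gamma = gamma, grp = grp,
                    sidx = sidx, Gind = Gind, m = m, h = x$h, w = x$w, n = x$n))
}

group_norm_backward <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout$mat * xhat)
  dbeta <- colSums(dout$mat)
  dxhat <- row_mul(dout$mat, cache$gamma)
  s1 <- rowsum(dxhat, cache$sidx, reorder = FALSE) %*% cache$Gind
  s2 <- rowsum(dxhat * xhat, cache$sidx, reorder = FALSE) %*% cache$Gind
  s1f <- s1[cache$sidx, cache$grp, drop = FALSE]
  s2f <- s2[cache$sidx, cache$grp, drop = FALSE]
  dx <- cache$isf * (dxhat - (s1f + xhat * s2f) / cache$m)
  list(dx = tensor_new(dx, cache$h, cache$w, cache$n),
       dgamma = dgamma, dbeta = dbeta)
}

# Batch normalization over all rows (batch x spatial) per channel, with
# running statistics for evaluation mode. In single-device runs the "batch"
# is the union of patches in the step, i.e. ordinary per-step statistics.
batch_norm_forward <- function(x, gamma, beta, running, training,
                               momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x$mat)
    ex2 <- colMeans(x$mat * x$mat)
    v <- pmax(ex2 - mu * mu, 0)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- row_mul(row_add(x$mat, -mu), invstd)
  y <- row_add(row_mul(xhat, gamma), beta)
  list(out = tensor_new(y, x$h, x$w, x$n), running = running,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    h = x$h, w = x$w, n = x$n, training = training))
}

batch_norm_backward <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout$mat * xhat)
  dbeta <- colSums(dout$mat)
  dxhat <- row_mul(dout$mat, cache$gamma)
  if (cache$training) {
    dx <- row_add(dxhat, -colMeans(dxhat)) -
      xhat * rep(colMeans(dxhat * xhat), each = nrow(xhat))
    dx <- row_mul(dx, cache$invstd)
  } else {
    dx <- row_mul(dxhat, cache$invstd)
  }
  list(dx = tensor_new(dx, cache$h, cache$w, cache$n),
       dgamma = dgamma, dbeta = dbeta)
}

# ---- elementwise / pooling / linear -----------------------------------------

relu_forward <- function(x) {
  mask <- x$mat > 0
  list(out = tensor_new(x$mat * mask, x$h, x$w, x$n), cache = mask)
}

relu_backward <- function(dout, mask) {
  tensor_new(dout$mat * mask, dout$h, dout$w, dout$n)
}

# k x k average pooling with stride k; trailing rows/cols that do not fill a
# window are dropped.
avg_pool_forward <- function(x, k) {
  oh <- x$h %/% k
  ow <- x$w %/% k
  samp_off <- (seq_len(x$n) - 1L) * x$h * x$w
  oi <- (seq_len(oh) - 1L) * k + 1L
  oj <- (seq_len(ow) - 1L) * k + 1L
  acc <- matrix(0, x$n * oh * ow, ncol(x$mat))
  ridx <- vector("list", k * k)
  m <- 1L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      plin <- outer(oi + di, (oj + dj - 1L) * x$h, "+")
      idx <- as.vector(outer(as.vector(plin), samp_off, "+"))
      ridx[[m]] <- idx
      acc <- acc + x$mat[idx, , drop = FALSE]
      m <- m + 1L
    }
  }
  list(out = tensor_new(acc / (k * k), oh, ow, x$n),
       cache = list(ridx = ridx, k = k, h = x$h, w = x$w, n = x$n,
                    C = ncol(x$mat)))
}

avg_pool_backward <- function(dout, cache) {
  dx <- matrix(0, cache$n * cache$h * cache$w, cache$C)
  g <- dout$mat / (cache$k * cache$k)
  for (idx in cache$ridx) dx[idx, ] <- dx[idx, ] + g
  tensor_new(dx, cache$h, cache$w, cache$n)
}

# Global average pooling: tensor -> (n, C) matrix.
gap_forward <- function(x) {
  sidx <- rep(seq_len(x$n), each = x$h * x$w)
  list(out = unname(rowsum(x$mat, sidx, reorder = FALSE)) / (x$h * x$w),
       cache = list(h = x$h, w = x$w, n = x$n))
}

gap_backward <- function(dout, cache) {
  dx <- dout[rep(seq_len(cache$n), each = cache$h * cache$w), , drop = FALSE] /
    (cache$h * cache$w)
  tensor_new(dx, cache$h, cache$w, cache$n)
}

linear_forward <- function(x, W, b = NULL) {
  y <- x %*% W
  if (!is.null(b)) y <- row_add(y, b)
  list(out = y, cache = list(x = x, W = W, has_b = !is.null(b)))
}

linear_backward <- function(dout, cache) {
  out <- list(dx = dout %*% t(cache$W), dW = crossprod(cache$x, dout))
  if (cache$has_b) out$db <- colSums(dout)
  out
}

# ---- parameter initialization and Adam --------------------------------------

init_conv_w <- function(kh, kw, cin, cout) {
  W <- matrix(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
              kh * kw * cin, cout)
  attr(W, "kernel") <- c(kh, kw)
  W
}

adam_init <- function(params) {
  zl <- lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
  list(m = zl, v = zl, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]][] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]][] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]][] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# elementwise add of two named grad lists (for gradient accumulation)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
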
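cfg_small <- gmic3d_config("desk", K = 2L)
model <- gmic3d_init(cfg_small, seed = 7)

test_that("forward pass produces coherent two-stage outputs", {
  v <- rand_volume(64, 64, 4, seed = 71)
  o <- gmic3d_forward(model, v)
  expect_named(o$p_global, c("benign", "malignant"))
  expect_named(o$p_local, c("benign", "malignant"))
  expect_true(all(o$p_global >= 0 & o$p_global <= 1))
  expect_true(all(o$p_local > 0 & o$p_local < 1))
  expect_equal(o$p_final, (o$p_global + o$p_local) / 2)
  g <- 64L %/% cfg_small$backbone_downsample
  expect_identical(dim(o$saliency), c(g, g, 4L, 2L))
  expect_identical(nrow(o$locations), 2L)
  expect_equal(sum(o$alpha), 1, tolerance = 1e-6)
  # deterministic in inference mode
  o2 <- gmic3d_forward(model, v)
  expect_identical(o$p_final, o2$p_final)
  # p_global agrees with the exported pooling on the returned saliency
  expect_equal(unname(o$p_global), unname(global_predict(o$saliency, cfg_small$t)),
               tolerance = 1e-12)
})

test_that("model initialization is seeded and structured", {
  m1 <- gmic3d_init(cfg_small, seed = 1)
  m2 <- gmic3d_init(cfg_small, seed = 1)
  m3 <- gmic3d_init(cfg_small, seed = 2)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params$att_V, m3$params$att_V))
  expect_true(all(m1$params$seg_W == cfg_small$omega))
  expect_true(all(m1$params$head_W == 0))
  expect_s3_class(m1, "gmic3d")
  expect_false(m1$fitted)
})

test_that("loss closed forms", {
  mk_out <- function(pl, pg, sal = array(0, c(2, 2, 2, 2))) {
    list(p_local = pl, p_global = pg, saliency = sal)
  }
  # perfect predictions, zero saliency -> 0
  expect_equal(total_loss(c(1, 0), mk_out(c(1, 0), c(1, 0)), beta = 1), 0,
               tolerance = 1e-5)
  # all predictions 0.5, y = (0,0), zero saliency -> 4 ln 2
  expect_equal(total_loss(c(0, 0), mk_out(c(0.5, 0.5), c(0.5, 0.5)), 1),
               4 * log(2), tolerance = 1e-12)
  # separate BCEs, not BCE of the averaged prediction
  out <- mk_out(c(0.9, 0.5), c(0.1, 0.5))
  got <- total_loss(c(1, 0), out, beta = 0)
  sep <- -log(0.9) - log(0.1) + 2 * (-log(0.5))
  avg <- -log((0.9 + 0.1) / 2) + 2 * (-log(0.5))
  expect_equal(got, sep, tolerance = 1e-12)
  expect_gt(abs(got - avg), 1)
  # saliency L1 enters linearly with weight beta
  sal <- array(abs(rnorm(16)), c(2, 2, 2, 2))
  l0 <- total_loss(c(0, 0), mk_out(c(0.5, 0.5), c(0.5, 0.5), sal), 0)
  l1 <- total_loss(c(0, 0), mk_out(c(0.5, 0.5), c(0.5, 0.5), sal), 0.3)
  expect_equal(l1 - l0, 0.3 * sum(sal), tolerance = 1e-12)
  expect_equal(saliency_l1(array(c(-1, 2, -3), c(3, 1, 1))), 6)
  expect_error(total_loss(c(2, 0), mk_out(c(0.5, 0.5), c(0.5, 0.5))),
               "labels")
})

test_that("augmentation: identity case and exact integer shifts", {
  v <- rand_volume(16, 16, 2, seed = 72)
  a0 <- with_seed(1, augment_volume(v, max_shift = 0L, scale_jitter = 0))
  expect_equal(a0, v, ignore_attr = TRUE)
  expect_identical(attr(a0, "shift"), c(0L, 0L))
  # a pure integer shift moves pixels exactly, zero-padding the border
  a <- with_seed(3, augment_volume(v, max_shift = 3L, scale_jitter = 0))
  sh <- attr(a, "shift")
  if (any(sh != 0)) {
    src_r <- (1:16) - sh[1]
    src_c <- (1:16) - sh[2]
    ok_r <- src_r >= 1 & src_r <= 16
    ok_c <- src_c >= 1 & src_c <= 16
    expect_equal(a[ok_r, ok_c, 1], v[src_r[ok_r], src_c[ok_c], 1],
                 tolerance = 1e-12)
    expect_true(all(a[!ok_r, , 1] == 0))
  }
})

test_that("TTA averages stay within the per-pass prediction range", {
  v <- rand_volume(64, 64, 3, seed = 73)
  p <- with_seed(5, tta_predict(model, v, n_aug = 4))
  expect_named(p, c("benign", "malignant"))
  singles <- with_seed(5, {
    vapply(1:4, function(i) {
      av <- augment_volume(v, model$config$max_shift, model$config$scale_jitter)
      gmic3d_forward(model, av)$p_final
    }, numeric(2))
  })
  expect_equal(unname(p), unname(rowMeans(singles)), tolerance = 1e-12)
  expect_true(all(p >= apply(singles, 1, min) - 1e-12))
  expect_true(all(p <= apply(singles, 1, max) + 1e-12))
})

test_that("training-step gradients match finite differences end to end", {
  # tiny but complete model; checks representative parameters of every block
  v <- rand_volume(64, 64, 2, seed = 74)
  y <- c(1, 0)
  m <- gmic3d_init(gmic3d_config("desk", K = 2L, beta = 1e-3), seed = 9)
  # give the zero-initialized head a nonzero value so local grads flow
  m$params$head_W[] <- with_seed(10, rnorm(length(m$params$head_W), sd = 0.1))
  st <- gmic3d:::gmic3d_train_step(m, v, y, training = FALSE)
  loss_at <- function(nm, val) {
    m2 <- m
    m2$params[[nm]][] <- val
    fw <- gmic3d_forward(m2, v)
    total_loss(y, fw, m2$config$beta)
  }
  for (nm in c("seg_W", "head_W", "att_w", "g_conv4_W", "l_fc_W", "g_gn2_g")) {
    x0 <- as.vector(m$params[[nm]])
    probe <- with_seed(11, sample(length(x0), min(6, length(x0))))
    for (i in probe) {
      eps <- 1e-5
      xp <- x0; xp[i] <- xp[i] + eps
      xm <- x0; xm[i] <- xm[i] - eps
      fd <- (loss_at(nm, xp) - loss_at(nm, xm)) / (2 * eps)
      an <- as.vector(st$grads[[nm]])[i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 5e-3)
    }
  }
})
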
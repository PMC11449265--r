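test_that("AUC equals the all-pairs Mann-Whitney oracle, ties included", {
  set.seed(81)
  for (i in 1:40) {
    n <- sample(4:100, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))   # both classes guaranteed
    scores <- if (i %% 2 == 0) {
      sample(seq(0, 1, by = 0.1), n, replace = TRUE)   # plenty of ties
    } else {
      rnorm(n)
    }
    expect_equal(auc(scores, labels), naive_auc(scores, labels))
  }
  expect_equal(auc(c(0, 1), c(0, 1)), 1)
  expect_equal(auc(c(1, 0), c(0, 1)), 0)
  expect_equal(auc(c(0.5, 0.5, 0.5), c(0, 1, 1)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "one class")
})

test_that("grouped AUC averages scores within groups first", {
  scores <- c(0.2, 0.4, 0.9, 0.7, 0.1)
  labels <- c(0, 0, 1, 1, 0)
  gid <- c("a", "a", "b", "b", "c")
  expect_equal(grouped_auc(scores, labels, gid),
               auc(c(0.3, 0.8, 0.1), c(0, 1, 0)))
  expect_error(grouped_auc(scores, c(0, 1, 1, 1, 0), gid), "inconsistent")
})

test_that("PxAP equals the threshold-enumeration oracle", {
  set.seed(82)
  for (i in 1:40) {
    n <- sample(5:100, 1)
    truth <- c(1, rbinom(n - 1, 1, 0.3))
    scores <- if (i %% 2 == 0) {
      sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    } else {
      runif(n)
    }
    expect_equal(pxap(scores, truth), naive_pxap(scores, truth))
  }
  # perfect ranking -> AP 1; worst ranking of a single positive at the bottom
  expect_equal(pxap(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(pxap(c(0.1, 0.5, 0.9), c(1, 0, 0)), 1 / 3)
  expect_error(pxap(runif(4), rep(0, 4)), "empty truth")
})

test_that("Dice closed forms and the threshold sweep", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(1 - a, a), 0)
  b <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(dice(b, a), 2 * 1 / (1 + 2))
  expect_error(dice(a, matrix(0, 2, 2)), "empty truth")

  sal <- matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2)
  truth <- matrix(c(1, 1, 0, 0), 2, 2)
  d <- dice_sweep(sal, truth)
  expect_equal(as.numeric(d), 1)
  sw <- attr(d, "sweep")
  expect_identical(nrow(sw), 19L)
  expect_true(all(sw$dice >= 0 & sw$dice <= 1))
})

test_that("max projection and block-max mask downsampling", {
  x <- array(0, c(2, 2, 3)); x[1, 2, 2] <- 5; x[1, 2, 3] <- 2
  expect_equal(max_project(x), matrix(c(0, 0, 5, 0), 2, 2))
  m <- matrix(0, 8, 8); m[3, 6] <- 1
  dm <- downsample_mask(m, 4L)
  expect_identical(dim(dm), c(2L, 2L))
  expect_equal(dm, matrix(c(0, 0, 1, 0), 2, 2))
  # a single voxel anywhere survives downsampling (small-object preservation)
  m3 <- array(0, c(8, 8, 2)); m3[8, 1, 2] <- 1
  d3 <- downsample_mask(m3, 4L)
  expect_equal(sum(d3), 1)
  expect_equal(d3[2, 1, 2], 1)
})

test_that("MAC counting is additive and linear in depth for the global path", {
  l1 <- list(type = "conv", c_in = 1, c_out = 4, kernel = c(3, 3),
             out_shape = c(8, 8))
  l2 <- list(type = "linear", c_in = 10, c_out = 3)
  expect_equal(count_macs(list(l1)), 8 * 8 * 1 * 4 * 9)
  expect_equal(count_macs(list(l2)), 30)
  expect_equal(count_macs(list(l1, l2)),
               count_macs(list(l1)) + count_macs(list(l2)))
  expect_equal(count_macs(list(c(l1, times = 5))), 5 * count_macs(list(l1)))
  expect_error(count_macs(list(list(type = "conv", c_in = 1, c_out = 1))),
               "needs kernel")
  expect_error(count_macs(list(list(type = "pool"))), "unknown layer")

  cfg <- gmic3d_config("desk")
  macs_of <- function(D) {
    spec <- gmic3d_layer_spec(cfg, c(64, 64, D))
    glob <- Filter(function(l) grepl("global|segmentation", l$name), spec)
    loc <- Filter(function(l) !grepl("global|segmentation", l$name), spec)
    c(g = count_macs(glob), l = count_macs(loc))
  }
  m4 <- macs_of(4); m8 <- macs_of(8); m16 <- macs_of(16)
  expect_equal(m8[["g"]] / m4[["g"]], 2)    # global module linear in D
  expect_equal(m16[["g"]] / m4[["g"]], 4)
  expect_equal(m8[["l"]], m4[["l"]])        # local module constant in D
  expect_equal(m16[["l"]], m4[["l"]])
})

test_that("patch coverage reproduces simple geometry", {
  expect_equal(as.numeric(patch_coverage(c(100, 100), 4, 10)), 4)
  expect_equal(as.numeric(patch_coverage(c(100, 100, 10), 4, 10)), 0.4)
  expect_equal(attr(patch_coverage(c(64, 64), 1, 32), "raw"), 25)
})

test_that("operating point and bootstrap CI behave sensibly", {
  scores <- c(0.1, 0.2, 0.6, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  op <- operating_point(scores, labels, at = c(sensitivity = 1))
  expect_equal(op[["sensitivity"]], 1)
  expect_equal(op[["threshold"]], 0.7)
  expect_equal(op[["specificity"]], 1)
  ci <- bootstrap_ci(scores, labels, n_boot = 200, seed = 3)
  expect_equal(ci[["estimate"]], 1)
  expect_true(ci[["lower"]] <= ci[["estimate"]])
  expect_true(ci[["upper"]] >= ci[["estimate"]] - 1e-12)
})

test_that("AUC agrees with pROC on random data", {
  set.seed(83)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(auc(scores, labels), ref, tolerance = 1e-12)
})
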
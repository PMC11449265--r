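# Fast training smoke tests on a handful of tiny phantoms; the full-scale
# learning test lives in test-acceptance.R.

mini_data <- local({
  spec <- phantom_spec()
  make <- function(n, off) lapply(seq_len(n), function(i) {
    ph <- generate_phantom(spec, seed = derive_seed(77, i + off), D = 2L)
    list(volume = ph$volume, labels = ph$labels, id = paste0("v", i + off))
  })
  # small val set with both malignant classes present
  val <- make(20, 100)
  ym <- vapply(val, function(s) s$labels[[2]], numeric(1))
  list(train = make(8, 0), val = val[c(which(ym == 1)[1:2], which(ym == 0)[1:2])])
})

cfg_fit <- gmic3d_config("desk", epochs = 2L, K = 2L, tta_count = 2L)

test_that("gmic3d() fits, logs, checkpoints, and is reproducible", {
  f1 <- gmic3d(mini_data, cfg_fit, seed = 3, augment = FALSE)
  expect_s3_class(f1, "gmic3d")
  expect_true(f1$fitted)
  expect_identical(nrow(f1$log), 2L)
  expect_true(all(c("train_loss", "val_auc_malignant") %in% names(f1$log)))
  # checkpoints select on the mean AUC over the two classes
  sel <- mapply(function(b, m) mean(c(if (!is.na(b)) b, m)),
                f1$log$val_auc_benign, f1$log$val_auc_malignant)
  expect_equal(f1$best_val_auc, max(sel))
  expect_true(f1$best_epoch %in% which(f1$log$best))
  f2 <- gmic3d(mini_data, cfg_fit, seed = 3, augment = FALSE)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$log$train_loss, f2$log$train_loss)
  f3 <- gmic3d(mini_data, cfg_fit, seed = 4, augment = FALSE)
  expect_false(identical(f1$params, f3$params))
})

test_that("fit validates its inputs", {
  expect_error(gmic3d(list(train = list(), val = mini_data$val), cfg_fit),
               "empty training")
  expect_error(gmic3d(list(train = mini_data$train, val = list()), cfg_fit),
               "empty validation")
  oneclass <- mini_data$val[vapply(mini_data$val,
                                   function(s) s$labels[[2]] == 0, logical(1))]
  expect_error(gmic3d(list(train = mini_data$train, val = oneclass), cfg_fit),
               "single malignant class")
  expect_error(gmic3d(42, cfg_fit), "data must be")
  expect_error(gmic3d(data.frame(id = 1), cfg_fit), "split column")
})

test_that("S3 methods print, summarize, predict and plot", {
  f <- gmic3d(mini_data, cfg_fit, seed = 3, augment = FALSE)
  expect_output(print(f), "fitted: 2 epochs")
  expect_output(print(gmic3d_init(cfg_fit)), "unfitted")
  expect_output(s <- summary(f), "Training log")
  expect_identical(s, f$log)
  expect_identical(coef(f), f$params)

  pr <- predict(f, mini_data$val)
  expect_identical(nrow(pr), 4L)
  expect_true(all(pr$p_benign > 0 & pr$p_benign < 1))
  expect_true(all(c("p_global_malignant", "p_local_malignant") %in% names(pr)))
  expect_equal(pr$p_malignant,
               (pr$p_global_malignant + pr$p_local_malignant) / 2)
  # single volume and full outputs
  pv <- predict(f, mini_data$val[[1]]$volume)
  expect_identical(nrow(pv), 1L)
  fu <- predict(f, mini_data$val[1:2], type = "full")
  expect_length(fu, 2L)
  expect_identical(dim(fu[[1]]$saliency)[4], 2L)
  # tta path
  pt <- with_seed(1, predict(f, mini_data$val[1:2], tta = TRUE))
  expect_identical(nrow(pt), 2L)

  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_silent(plot(f))
  expect_silent(plot_saliency_overlay(mini_data$val[[1]]$volume,
                                      gmic3d_forward(f, mini_data$val[[1]]$volume),
                                      slice = 1L))
  grDevices::dev.off()
  expect_true(file.size(tmp) > 0)
  expect_error(plot(gmic3d_init(cfg_fit)), "no training log")
})

test_that("fitting from an on-disk manifest works end to end", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(10, phantom_spec(), seed = 6, out_dir = dir,
                          overwrite = TRUE)
  # assign the split by hand so both malignant classes land in val
  ord <- order(man$y_m)
  man$split <- "train"
  man$split[c(ord[1], ord[nrow(man)])] <- "val"   # one negative, one positive
  csv <- file.path(dir, "manifest.csv")
  write_manifest(man, csv)
  f <- gmic3d(csv, gmic3d_config("desk", epochs = 1L, K = 2L), seed = 2,
              augment = FALSE)
  expect_true(f$fitted)
  pr <- predict(f, csv)
  expect_identical(nrow(pr), nrow(man))
})

test_that("evaluate_classification and evaluate_segmentation integrate", {
  spec <- phantom_spec()
  # five groups of two views: the second view re-renders the first view's
  # lesion layout with independent noise, so labels agree within a group
  ss <- unlist(lapply(1:5, function(g) {
    ph1 <- generate_phantom(spec, seed = derive_seed(88, g), D = 2L)
    ph2 <- generate_phantom(spec, seed = derive_seed(88, 1000 + g), D = 2L,
                            lesion_config = ph1$metadata$lesions)
    mapply(function(ph, v) {
      list(volume = ph$volume, labels = ph$labels, masks = ph$masks,
           id = paste0("e", g, "v", v), group_id = g)
    }, list(ph1, ph2), 1:2, SIMPLIFY = FALSE)
  }), recursive = FALSE)
  model <- gmic3d_init(gmic3d_config("desk", K = 2L), seed = 1)
  ym <- vapply(ss, function(s) s$labels[[2]], numeric(1))
  yb <- vapply(ss, function(s) s$labels[[1]], numeric(1))
  if (length(unique(ym)) == 2 && length(unique(yb)) == 2) {
    cl <- evaluate_classification(model, ss)
    expect_identical(nrow(cl$scores), 10L)
    expect_true(cl$auc_malignant >= 0 && cl$auc_malignant <= 1)
    expect_true(!is.null(cl$grouped_auc_malignant))
  }
  seg <- evaluate_segmentation(model, ss)
  expect_true(nrow(seg) >= 1)
  expect_true(all(seg$pxap >= 0 & seg$pxap <= 1))
  expect_true(all(seg$dice >= 0 & seg$dice <= 1))
  expect_true(all(seg$class %in% c("benign", "malignant")))
})
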
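#' Fit the two-stage weakly-supervised classifier
#'
#' Trains the full model (global per-slice encoder + saliency head with
#' top-t\% pooling, greedy patch retrieval, gated-attention local module)
#' end-to-end with Adam on the summed per-module BCE losses plus the
#' saliency L1 penalty, using gradient accumulation over
#' `config$grad_accum` volumes per update. The checkpoint with the best
#' validation AUC (mean over the two classes) is kept; training stops early
#' after `config$patience` epochs without improvement. Fully reproducible
#' given `seed` on a single device.
#'
#' @param data either a list with elements `train` and `val` (each a list of
#'   samples: `list(volume = (H,W,D) array, labels = c(y_b, y_m))`, e.g.
#'   from [generate_phantom()]), or a manifest data.frame / CSV path with a
#'   `split` column (volumes are loaded from disk).
#' @param config a [gmic3d_config()].
#' @param seed integer seed controlling initialization, shuffling,
#'   augmentation and retrieval sampling.
#' @param augment logical; apply random shift/resize augmentation to each
#'   training volume.
#' @param verbose print one line per epoch.
#' @return an object of class `gmic3d` with the trained parameters, the
#'   configuration, and a per-epoch `log` data.frame (epoch, train_loss,
#'   val_auc_benign, val_auc_malignant, best flag).
#' @seealso [predict.gmic3d()], [gmic3d_forward()], [tta_predict()]
#' @export
gmic3d <- function(data, config = gmic3d_config(), seed = 1L,
                   augment = TRUE, verbose = FALSE) {
  data <- resolve_training_data(data)
  train <- data$train
  val <- data$val
  if (length(train) == 0L) stop("empty training split")
  if (length(val) == 0L) stop("empty validation split")
  val_ym <- vapply(val, function(s) s$labels[[2]], numeric(1))
  if (length(unique(val_ym)) < 2L) {
    stop("validation set contains a single malignant class; AUC undefined")
  }

  model <- gmic3d_init(config, seed = seed)
  cfg <- model$config
  opt <- adam_init(model$params)
  log_rows <- list()
  best <- list(auc = -Inf, params = model$params, buffers = model$buffers,
               epoch = 0L)
  since_best <- 0L

  with_seed(derive_seed(seed, 9999L), {
    for (epoch in seq_len(cfg$epochs)) {
      t0 <- proc.time()[3]
      idx <- sample(length(train))
      acc <- NULL
      n_acc <- 0L
      tot_loss <- 0
      for (i in idx) {
        s <- train[[i]]
        v <- s$volume
        if (augment && (cfg$max_shift > 0 || cfg$scale_jitter > 0)) {
          v <- augment_volume(v, cfg$max_shift, cfg$scale_jitter)
        }
        st <- gmic3d_train_step(model, v, s$labels)
        model$buffers <- st$buffers
        tot_loss <- tot_loss + st$loss
        acc <- grads_add(acc, st$grads)
        n_acc <- n_acc + 1L
        if (n_acc == cfg$grad_accum || i == idx[length(idx)]) {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / n_acc
          up <- adam_step(model$params, acc, opt, cfg$lr)
          model$params <- up$params
          opt <- up$state
          acc <- NULL
          n_acc <- 0L
        }
      }
      scores <- vapply(val, function(s) {
        gmic3d_forward(model, s$volume)$p_final
      }, numeric(2))
      val_yb <- vapply(val, function(s) s$labels[[1]], numeric(1))
      auc_b <- if (length(unique(val_yb)) == 2L) auc(scores[1, ], val_yb) else NA
      auc_m <- auc(scores[2, ], val_ym)
      # checkpoint on the mean AUC over the classes: selecting on a single
      # class is noisy on small validation sets
      sel <- mean(c(if (!is.na(auc_b)) auc_b, auc_m))
      improved <- sel > best$auc
      if (improved) {
        best <- list(auc = sel, params = model$params,
                     buffers = model$buffers, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = tot_loss / length(train),
        val_auc_benign = auc_b, val_auc_malignant = auc_m,
        seconds = proc.time()[3] - t0, best = improved)
      if (verbose) {
        log_msg("INFO", sprintf(
          "epoch %d loss %.4f val AUC (b/m) %.3f/%.3f%s", epoch,
          tot_loss / length(train), auc_b, auc_m,
          if (improved) " *" else ""))
      }
      if (since_best >= cfg$patience) break
    }
  })

  model$params <- best$params
  model$buffers <- best$buffers
  model$fitted <- TRUE
  model$log <- do.call(rbind, log_rows)
  model$best_epoch <- best$epoch
  model$best_val_auc <- best$auc
  model$seed <- seed
  model
}

resolve_training_data <- function(data) {
  if (is.list(data) && !is.data.frame(data) &&
      all(c("train", "val") %in% names(data))) {
    return(data)
  }
  if (is.character(data)) data <- read_manifest(data)
  if (is.data.frame(data)) {
    if (is.null(data$split)) stop("manifest needs a split column")
    return(list(train = load_manifest_samples(data, "train"),
                val = load_manifest_samples(data, "val")))
  }
  stop("data must be list(train=, val=) of samples, a manifest data.frame, ",
       "or a manifest CSV path")
}

# ---- S3 methods ----------------------------------------------------------------

#' @export
print.gmic3d <- function(x, ...) {
  cfg <- x$config
  cat("Two-stage weakly-supervised 3D stack classifier\n")
  cat(sprintf("  profile: %s | backbone width %d (downsample %d) | patch %dpx | K=%d | zeta=%d | t=%g%%\n",
              cfg$profile, cfg$backbone_width, cfg$backbone_downsample,
              cfg$patch_size, cfg$K, cfg$zeta, cfg$t))
  if (isTRUE(x$fitted)) {
    cat(sprintf("  fitted: %d epochs (best %d), best val mean AUC %.3f\n",
                nrow(x$log), x$best_epoch, x$best_val_auc))
  } else {
    cat("  unfitted (constant-initialized segmentation layer, omega =",
        cfg$omega, ")\n")
  }
  invisible(x)
}

#' @export
summary.gmic3d <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat("\nTraining log:\n")
    print(object$log[, c("epoch", "train_loss", "val_auc_benign",
                         "val_auc_malignant", "best")],
          row.names = FALSE, digits = 4)
  }
  invisible(object$log)
}

#' @export
coef.gmic3d <- function(object, ...) object$params

#' Predict from a fitted model
#'
#' @param object a `gmic3d` model.
#' @param newdata a single `(H, W, D)` volume, one sample
#'   (`list(volume=, ...)`), a list of samples, or a manifest
#'   data.frame/CSV path.
#' @param type `"prob"` returns a data.frame of final/global/local class
#'   probabilities per volume; `"full"` returns the complete forward output
#'   (saliency, patch locations, attention) per volume.
#' @param tta average over `object$config$tta_count` augmented passes.
#' @param ... unused.
#' @export
predict.gmic3d <- function(object, newdata, type = c("prob", "full"),
                           tta = FALSE, ...) {
  type <- match.arg(type)
  samples <- as_sample_list(newdata)
  if (type == "full") {
    return(lapply(samples, function(s) gmic3d_forward(object, s$volume)))
  }
  rows <- lapply(samples, function(s) {
    if (tta) {
      p <- tta_predict(object, s$volume)
      data.frame(id = s$id %||% NA_character_,
                 p_benign = p[[1]], p_malignant = p[[2]])
    } else {
      o <- gmic3d_forward(object, s$volume)
      data.frame(id = s$id %||% NA_character_,
                 p_benign = o$p_final[[1]], p_malignant = o$p_final[[2]],
                 p_global_benign = o$p_global[[1]],
                 p_global_malignant = o$p_global[[2]],
                 p_local_benign = o$p_local[[1]],
                 p_local_malignant = o$p_local[[2]])
    }
  })
  do.call(rbind, rows)
}

as_sample_list <- function(newdata) {
  if (is.array(newdata) && length(dim(newdata)) %in% c(2L, 3L)) {
    if (length(dim(newdata)) == 2L) newdata <- array(newdata, c(dim(newdata), 1L))
    return(list(list(volume = newdata, id = attr(newdata, "id"))))
  }
  if (is.character(newdata)) newdata <- read_manifest(newdata)
  if (is.data.frame(newdata)) return(load_manifest_samples(newdata))
  if (is.list(newdata) && !is.null(newdata$volume)) return(list(newdata))
  if (is.list(newdata)) return(newdata)
  stop("unsupported newdata")
}

#' @export
plot.gmic3d <- function(x, ...) {
  if (is.null(x$log)) stop("nothing to plot: model has no training log")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$log$epoch, x$log$train_loss, type = "b", pch = 16,
       xlab = "epoch", ylab = "mean training loss", main = "loss")
  plot(x$log$epoch, x$log$val_auc_malignant, type = "b", pch = 16,
       ylim = c(0, 1), xlab = "epoch", ylab = "validation AUC",
       main = "validation AUC")
  graphics::lines(x$log$epoch, x$log$val_auc_benign, type = "b", lty = 2)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("bottomright", c("malignant", "benign"), lty = 1:2,
                   pch = c(16, 1), bty = "n")
  invisible(x)
}

#' Overlay retrieved patches and saliency on a slice
#'
#' Draws the given slice in gray, tints it by the summed class saliency
#' (upsampled by the downsample factor), and outlines the retrieved patch
#' rectangles that fall on this slice. Useful for writing Fig.-style
#' localization panels to PNG.
#'
#' @param volume `(H, W, D)` array.
#' @param output result of [gmic3d_forward()] for that volume.
#' @param slice 1-based slice index to show.
#' @param ... passed to [graphics::image()].
#' @export
plot_saliency_overlay <- function(volume, output, slice = 1L, ...) {
  H <- dim(volume)[1]; W <- dim(volume)[2]
  img <- t(volume[H:1, , slice])
  graphics::image(img, col = grDevices::gray.colors(128, 0, 1),
                  axes = FALSE, useRaster = TRUE, ...)
  sal <- output$saliency[, , slice, 1] + output$saliency[, , slice, 2]
  h <- nrow(sal); w <- ncol(sal)
  sal_t <- t(sal[h:1, , drop = FALSE])
  graphics::image(sal_t, col = grDevices::adjustcolor(
    grDevices::hcl.colors(64, "Reds", rev = TRUE), alpha.f = 0.35),
    add = TRUE, useRaster = TRUE)
  locs <- output$locations
  sel <- locs$slice == (slice - 1L)
  if (any(sel)) {
    for (k in which(sel)) {
      x0 <- locs$left[k] / W; x1 <- (locs$left[k] + locs$size[k]) / W
      y0 <- 1 - (locs$top[k] + locs$size[k]) / H; y1 <- 1 - locs$top[k] / H
      graphics::rect(x0, y0, x1, y1, border = "blue", lwd = 2)
    }
  }
  invisible(NULL)
}
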
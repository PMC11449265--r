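# Classification metrics (image-wise and group-averaged AUC), weakly-
# supervised segmentation metrics (DSC, PxAP) under the depth max-projection
# protocol, and analytic compute accounting (MACs, patch coverage).

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the fraction of
#' (positive, negative) pairs ranked correctly, ties counted one half
#' (mid-rank method).
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length; both classes must be
#'   present.
#' @return value in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Group-averaged AUC
#'
#' Averages scores within each group (e.g. the two views of one subject)
#' and computes the AUC over groups. Labels must be consistent within each
#' group.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector.
#' @param group_id group identifier per record.
#' @return value in `[0, 1]`.
#' @export
grouped_auc <- function(scores, labels, group_id) {
  stopifnot(length(scores) == length(labels),
            length(scores) == length(group_id))
  lab_per_group <- tapply(labels, group_id, function(x) {
    u <- unique(x)
    if (length(u) > 1L) stop("inconsistent labels within a group")
    u
  })
  score_per_group <- tapply(scores, group_id, mean)
  auc(as.numeric(score_per_group), as.numeric(lab_per_group))
}

#' Max-projection along depth
#'
#' @param plane `(h, w, D)` array (a matrix is treated as D = 1).
#' @return `(h, w)` matrix of elementwise maxima over depth.
#' @export
max_project <- function(plane) {
  if (is.matrix(plane)) return(plane)
  dm <- dim(plane)
  stopifnot(length(dm) == 3L, dm[3] >= 1L)
  apply(plane, c(1, 2), max)
}

#' Dice similarity coefficient
#'
#' @param pred_mask,truth_mask binary arrays of identical shape; the truth
#'   mask must be non-empty.
#' @return `2|P.T| / (|P| + |T|)` in `[0, 1]`.
#' @export
dice <- function(pred_mask, truth_mask) {
  stopifnot(all(dim(pred_mask) == dim(truth_mask)))
  p <- pred_mask > 0
  t <- truth_mask > 0
  if (!any(t)) stop("empty truth mask")
  denom <- sum(p) + sum(t)
  if (denom == 0) return(0)
  2 * sum(p & t) / denom
}

#' Dice over a threshold sweep
#'
#' The saliency map is min-max normalized and binarized at each of 19
#' thresholds 0.05..0.95; Dice is reported at the best threshold with the
#' full sweep attached (no single calibration threshold is assumed).
#'
#' @param saliency numeric array (typically a depth max-projection).
#' @param truth_mask binary array, same shape, non-empty.
#' @param thresholds sweep values.
#' @return best Dice, with attributes `threshold` and `sweep`.
#' @export
dice_sweep <- function(saliency, truth_mask,
                       thresholds = seq(0.05, 0.95, by = 0.05)) {
  s <- minmax_normalize(saliency)
  vals <- vapply(thresholds, function(th) dice(s >= th, truth_mask),
                 numeric(1))
  best <- which.max(vals)
  structure(vals[best], threshold = thresholds[best],
            sweep = data.frame(threshold = thresholds, dice = vals))
}

#' Pixel average precision
#'
#' Exact average precision of the pixel ranking by saliency value against
#' the binary truth: the PR curve is evaluated at every distinct score
#' (ties grouped), and AP is the step-wise sum of precision times recall
#' increment.
#'
#' @param saliency_plane numeric array.
#' @param truth_mask binary array, same shape, non-empty.
#' @return value in `[0, 1]`.
#' @export
pxap <- function(saliency_plane, truth_mask) {
  stopifnot(length(saliency_plane) == length(truth_mask))
  t <- as.numeric(truth_mask > 0)
  if (sum(t) == 0) stop("empty truth mask")
  s <- as.numeric(saliency_plane)
  o <- order(s, decreasing = TRUE)
  s <- s[o]; t <- t[o]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))         # last index of each distinct score
  tp <- cumsum(t)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / sum(t)
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Downsample a truth mask to the saliency grid by block maximum
#'
#' Any lesion voxel inside a saliency cell marks the cell, preserving small
#' objects.
#'
#' @param mask binary `(H, W)` matrix or `(H, W, D)` array.
#' @param factor integer downsampling factor (the backbone downsample).
#' @return binary array of shape `ceiling(dim / factor)` (depth unchanged).
#' @export
downsample_mask <- function(mask, factor) {
  f <- as.integer(factor)
  block1 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    bi <- (seq_len(h) - 1L) %/% f + 1L
    bj <- (seq_len(w) - 1L) %/% f + 1L
    agg <- rowsum(m, bi)                 # sums per row block
    agg <- t(rowsum(t(agg), bj))
    unname((agg > 0) + 0)
  }
  if (is.matrix(mask)) return(block1(mask))
  dm <- dim(mask)
  out <- array(0, c(ceiling(dm[1] / f), ceiling(dm[2] / f), dm[3]))
  for (d in seq_len(dm[3])) out[, , d] <- block1(mask[, , d])
  out
}

#' Analytic multiply-accumulate count
#'
#' Sums per-layer MAC counts from a symbolic layer list without executing
#' anything: a convolution contributes
#' `prod(out_shape) * c_in * c_out * prod(kernel)` and a linear layer
#' `c_in * c_out`. A `times` field (default 1) multiplies a layer's count
#' (e.g. per-slice layers repeated D times, per-patch layers K times).
#'
#' @param layers list of layer specs: `list(type = "conv", c_in=, c_out=,
#'   kernel=, out_shape=, times=)` or `list(type = "linear", c_in=, c_out=,
#'   times=)`.
#' @return total MAC count (numeric scalar).
#' @export
count_macs <- function(layers) {
  total <- 0
  for (l in layers) {
    times <- l$times %||% 1
    macs <- switch(l$type,
      conv = {
        if (is.null(l$out_shape) || is.null(l$kernel)) {
          stop("conv layer needs kernel and out_shape")
        }
        prod(l$out_shape) * l$c_in * l$c_out * prod(l$kernel)
      },
      linear = l$c_in * l$c_out,
      stop("unknown layer type: ", l$type))
    total <- total + macs * times
  }
  total
}

#' Symbolic layer list of the full model
#'
#' Builds the [count_macs()] spec for a given configuration and input shape:
#' the global per-slice encoder and segmentation layer run once per slice
#' (counts scale linearly in D), while the local module runs once per
#' retrieved patch (constant in D).
#'
#' @param config a [gmic3d_config()].
#' @param input_shape `(H, W, D)`.
#' @return list of layer specs.
#' @export
gmic3d_layer_spec <- function(config, input_shape) {
  H <- input_shape[1]; W <- input_shape[2]; D <- input_shape[3]
  cw <- config$backbone_width
  k <- config$backbone_downsample %/% 4L
  h1 <- conv_out_dim(H, 5L, 2L, 2L); w1 <- conv_out_dim(W, 5L, 2L, 2L)
  h2 <- conv_out_dim(h1, 3L, 2L, 1L); w2 <- conv_out_dim(w1, 3L, 2L, 1L)
  hs <- h2 %/% k; ws <- w2 %/% k
  p <- config$patch_size
  lw <- config$local_width
  p1 <- conv_out_dim(p, 5L, 2L, 2L)
  p2 <- conv_out_dim(p1, 3L, 2L, 1L)
  c(
    list(
      list(type = "conv", c_in = 1, c_out = cw, kernel = c(5, 5),
           out_shape = c(h1, w1), times = D, name = "global conv1"),
      list(type = "conv", c_in = cw, c_out = cw, kernel = c(3, 3),
           out_shape = c(h2, w2), times = D, name = "global conv2"),
      list(type = "conv", c_in = cw, c_out = cw, kernel = c(3, 3),
           out_shape = c(h2, w2), times = D, name = "global conv3"),
      list(type = "conv", c_in = cw, c_out = cw, kernel = c(3, 3),
           out_shape = c(h2, w2), times = D, name = "global conv4"),
      list(type = "conv", c_in = cw, c_out = 2, kernel = c(1, 1),
           out_shape = c(hs, ws), times = D, name = "segmentation 1x1")
    ),
    list(
      list(type = "conv", c_in = 1, c_out = lw, kernel = c(5, 5),
           out_shape = c(p1, p1), times = config$K, name = "local conv1"),
      list(type = "conv", c_in = lw, c_out = lw, kernel = c(3, 3),
           out_shape = c(p2, p2), times = config$K, name = "local conv2"),
      list(type = "conv", c_in = lw, c_out = lw, kernel = c(3, 3),
           out_shape = c(p2, p2), times = config$K, name = "local conv3"),
      list(type = "conv", c_in = lw, c_out = lw, kernel = c(3, 3),
           out_shape = c(p2, p2), times = config$K, name = "local conv4"),
      list(type = "linear", c_in = lw, c_out = config$S, times = config$K,
           name = "local fc"),
      list(type = "linear", c_in = config$S, c_out = config$L,
           times = 2 * config$K, name = "attention gates"),
      list(type = "linear", c_in = config$L, c_out = 1, times = config$K,
           name = "attention score"),
      list(type = "linear", c_in = config$S, c_out = 2, times = 1,
           name = "local head")
    )
  )
}

#' Fraction of the input covered by the retrieved patches
#'
#' @param image_shape `(H, W)` or `(H, W, D)`.
#' @param K number of patches.
#' @param patch_size patch side in pixels (or a length-2 vector).
#' @return percentage, rounded to 2 decimals for reporting; the raw value
#'   is in attribute `raw`.
#' @export
#' @examples
#' patch_coverage(c(2116, 1339), 8, 256)       # 18.50
#' patch_coverage(c(2116, 1339, 70), 8, 256)   # 0.26
patch_coverage <- function(image_shape, K, patch_size) {
  stopifnot(all(image_shape > 0), K >= 0)
  ph <- patch_size[1]
  pw <- if (length(patch_size) > 1L) patch_size[2] else patch_size[1]
  raw <- 100 * K * ph * pw / prod(image_shape)
  structure(round(raw, 2), raw = raw)
}

#' Classification metrics for a fitted model on a sample list
#'
#' @param model a fitted `gmic3d`.
#' @param samples list of samples (`volume`, `labels`, optional
#'   `group_id`).
#' @param tta use test-time augmentation.
#' @return list with `scores` (per-sample data.frame), `auc_benign`,
#'   `auc_malignant`, and when group ids are present the group-averaged
#'   AUCs.
#' @export
evaluate_classification <- function(model, samples, tta = FALSE) {
  score <- vapply(samples, function(s) {
    if (tta) tta_predict(model, s$volume)
    else gmic3d_forward(model, s$volume)$p_final
  }, numeric(2))
  yb <- vapply(samples, function(s) s$labels[[1]], numeric(1))
  ym <- vapply(samples, function(s) s$labels[[2]], numeric(1))
  gid <- vapply(samples, function(s) {
    as.character(s$group_id %||% s$id %||% NA_character_)
  }, character(1))
  out <- list(scores = data.frame(p_benign = score[1, ],
                                  p_malignant = score[2, ],
                                  y_b = yb, y_m = ym, group_id = gid),
              auc_benign = auc(score[1, ], yb),
              auc_malignant = auc(score[2, ], ym))
  if (!anyNA(gid)) {
    out$grouped_auc_benign <- grouped_auc(score[1, ], yb, gid)
    out$grouped_auc_malignant <- grouped_auc(score[2, ], ym, gid)
  }
  out
}

#' Weakly-supervised segmentation metrics on positive samples
#'
#' For each sample with a non-empty truth mask for a class, max-projects
#' both the class saliency plane and the truth mask along depth (the truth
#' mask is first block-max downsampled to the saliency grid) and computes
#' PxAP and best-threshold Dice, plus the inside/outside mean-saliency
#' ratio on the (un-projected) 3D grid. Samples without any lesion are
#' skipped.
#'
#' @param model a fitted `gmic3d`.
#' @param samples list of samples with `masks` (`(H, W, D, 2)` binary).
#' @return data.frame with one row per (sample, positive class):
#'   `id`, `class`, `dice`, `pxap`, `inside_outside_ratio`.
#' @export
evaluate_segmentation <- function(model, samples) {
  ds <- model$config$backbone_downsample
  rows <- list()
  for (s in samples) {
    if (is.null(s$masks)) next
    o <- gmic3d_forward(model, s$volume)
    for (k in 1:2) {
      m <- array(s$masks[, , , k], dim(s$masks)[1:3])
      if (!any(m > 0)) next
      mg <- downsample_mask(m, ds)
      sal <- array(o$saliency[, , , k], dim(o$saliency)[1:3])
      mg <- mg[seq_len(dim(sal)[1]), seq_len(dim(sal)[2]), , drop = FALSE]
      d2 <- dice_sweep(max_project(sal), max_project(mg))
      p2 <- pxap(max_project(sal), max_project(mg))
      inside <- mean(sal[mg > 0])
      outside <- mean(sal[mg == 0])
      rows[[length(rows) + 1L]] <- data.frame(
        id = s$id %||% NA_character_, class = c("benign", "malignant")[k],
        dice = as.numeric(d2), pxap = p2,
        inside_outside_ratio = inside / max(outside, 1e-12))
    }
  }
  do.call(rbind, rows)
}

#' Operating point and bootstrap utilities
#'
#' `operating_point()` reports sensitivity/specificity at the threshold
#' achieving a requested sensitivity (or specificity); `bootstrap_ci()`
#' gives percentile confidence intervals of a metric over resampled
#' records.
#'
#' @param scores,labels numeric scores and 0/1 labels.
#' @param at named target, e.g. `c(sensitivity = 0.9)` or
#'   `c(specificity = 0.95)`.
#' @return named vector with threshold, sensitivity, specificity.
#' @export
operating_point <- function(scores, labels, at = c(sensitivity = 0.9)) {
  stopifnot(length(at) == 1L, names(at) %in% c("sensitivity", "specificity"))
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(th, function(x) mean(scores[labels == 1] >= x), numeric(1))
  spec <- vapply(th, function(x) mean(scores[labels == 0] < x), numeric(1))
  i <- if (names(at) == "sensitivity") {
    which(sens >= at)[1]
  } else {
    rev(which(spec >= at))[1]
  }
  if (is.na(i)) i <- if (names(at) == "sensitivity") length(th) else 1L
  c(threshold = th[i], sensitivity = sens[i], specificity = spec[i])
}

#' @rdname operating_point
#' @param metric function of (scores, labels), e.g. [auc()].
#' @param n_boot number of bootstrap replicates.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @export
bootstrap_ci <- function(scores, labels, metric = auc, n_boot = 1000L,
                         conf = 0.95, seed = 1L) {
  n <- length(scores)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) < 2L) return(NA_real_)
      metric(scores[idx], labels[idx])
    }, numeric(1))
  })
  q <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       na.rm = TRUE)
  c(estimate = metric(scores, labels), lower = q[[1]], upper = q[[2]])
}
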
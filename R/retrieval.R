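# Greedy retrieval of K informative patches from the 3D saliency map, with
# suppression of the selected xy-footprint across +/- zeta neighboring slices
# and (during training) uniform resampling of the selected slice within the
# same window.

#' Min-max normalization of a saliency plane
#'
#' @param plane numeric array, finite.
#' @return same shape, values in `[0, 1]`; a constant plane maps to all
#'   zeros (degenerate-range convention).
#' @export
minmax_normalize <- function(plane) {
  stopifnot(all(is.finite(plane)))
  mn <- min(plane)
  mx <- max(plane)
  if (mx == mn) return(plane * 0)
  (plane - mn) / (mx - mn)
}

#' Combined retrieval criterion map
#'
#' Per-class min-max normalization of the two saliency planes followed by
#' their sum, giving the `(h, w, D)` criterion on which patches are
#' greedily selected. Entries lie in `[0, 2]`.
#'
#' @param saliency `(h, w, D, 2)` saliency array.
#' @return `(h, w, D)` array.
#' @export
combine_class_maps <- function(saliency) {
  dm <- dim(saliency)
  stopifnot(length(dm) == 4L, dm[4] == 2L)
  minmax_normalize(array(saliency[, , , 1], dm[1:3])) +
    minmax_normalize(array(saliency[, , , 2], dm[1:3]))
}

# rectangle size on the saliency grid corresponding to a patch in image space
grid_rect_size <- function(patch, img, grid) {
  max(1L, min(grid, as.integer(round_half_up(patch * grid / img))))
}

# Criterion of every rh x rw rectangle on one slice, by shifted-add
# accumulation in the same (column-major) order a naive sum would use, so
# exact zeros stay exact after suppression.
rect_criterion_slice <- function(plane, rh, rw) {
  nt <- nrow(plane) - rh + 1L
  nl <- ncol(plane) - rw + 1L
  acc <- matrix(0, nt, nl)
  for (dj in 0:(rw - 1L)) {
    for (di in 0:(rh - 1L)) {
      acc <- acc + plane[(1L:nt) + di, (1L:nl) + dj, drop = FALSE]
    }
  }
  acc
}

#' Greedy patch retrieval from a 3D saliency map
#'
#' Repeats K times: find the single-slice rectangle (of the saliency-grid
#' size corresponding to a `patch_size` square in image coordinates)
#' maximizing the summed criterion (ties broken by lexicographically
#' smallest (slice, top, left)); map it to image coordinates (scaled,
#' rounded, clipped so the full patch fits); then zero the criterion over
#' the rectangle's footprint across slices `d - zeta .. d + zeta`. During
#' training (and when D > 1) the selected slice is replaced by one drawn
#' uniformly from the same clipped window, as patch-level augmentation.
#'
#' @param saliency `(h, w, D, 2)` saliency array.
#' @param config a [gmic3d_config()] (fields `K`, `zeta`, `patch_size`), or
#'   a list with those fields.
#' @param image_shape integer `(H, W, D)` of the underlying volume.
#' @param training logical; enables slice resampling (uses the R RNG).
#' @return data.frame with K rows: `rank`, `slice`, `top`, `left` (0-based
#'   image coordinates of the patch corner) and `size`; attribute `grid`
#'   holds the selected saliency-grid rectangles (0-based, plus `rh`, `rw`)
#'   before slice resampling, and attribute `criterion` the criterion value
#'   at each pick.
#' @export
retrieve_roi_from_3d_image <- function(saliency, config, image_shape,
                                       training = FALSE) {
  dm <- dim(saliency)
  stopifnot(length(dm) == 4L, dm[4] == 2L)
  h <- dm[1]; w <- dm[2]; D <- dm[3]
  H <- image_shape[1]; W <- image_shape[2]
  if (image_shape[3] != D) stop("image_shape slice count does not match saliency")
  K <- as.integer(config$K)
  zeta <- as.integer(config$zeta)
  ph <- if (length(config$patch_size) == 2L) config$patch_size[1] else config$patch_size
  pw <- if (length(config$patch_size) == 2L) config$patch_size[2] else config$patch_size
  if (ph > H || pw > W) stop("patch larger than image")
  rh <- grid_rect_size(ph, H, h)
  rw <- grid_rect_size(pw, W, w)
  if (rh > h || rw > w) stop("saliency-grid rectangle larger than the grid")

  astar <- combine_class_maps(saliency)
  nt <- h - rh + 1L
  nl <- w - rw + 1L
  crit <- array(0, c(nt, nl, D))
  for (d in seq_len(D)) {
    crit[, , d] <- rect_criterion_slice(matrix(astar[, , d], h, w), rh, rw)
  }

  out <- data.frame(rank = seq_len(K), slice = NA_integer_,
                    top = NA_integer_, left = NA_integer_)
  grid <- data.frame(rank = seq_len(K), slice = NA_integer_,
                     top = NA_integer_, left = NA_integer_,
                     rh = rh, rw = rw)
  critval <- numeric(K)

  for (k in seq_len(K)) {
    best_v <- -Inf; best <- c(1L, 1L, 1L)
    for (d in seq_len(D)) {
      cd <- crit[, , d, drop = TRUE]
      if (!is.matrix(cd)) cd <- matrix(cd, nt, nl)
      m <- max(cd)
      if (m > best_v) {
        idx <- which(cd == m)
        rows <- ((idx - 1L) %% nt) + 1L
        cols <- ((idx - 1L) %/% nt) + 1L
        o <- order(rows, cols)[1L]
        best_v <- m
        best <- c(d, rows[o], cols[o])
      }
    }
    d <- best[1]; ti <- best[2]; tj <- best[3]
    grid$slice[k] <- d - 1L; grid$top[k] <- ti - 1L; grid$left[k] <- tj - 1L
    critval[k] <- best_v

    d_out <- d
    if (training && D > 1L) {
      lo <- max(1L, d - zeta)
      hi <- min(D, d + zeta)
      d_out <- if (lo == hi) lo else sample(lo:hi, 1L)
    }
    out$slice[k] <- d_out - 1L
    out$top[k] <- as.integer(clamp(round_half_up((ti - 1L) * H / h), 0, H - ph))
    out$left[k] <- as.integer(clamp(round_half_up((tj - 1L) * W / w), 0, W - pw))

    # suppression: zero the exact rectangle footprint across +/- zeta slices
    zlo <- max(1L, d - zeta)
    zhi <- min(D, d + zeta)
    astar[ti:(ti + rh - 1L), tj:(tj + rw - 1L), zlo:zhi] <- 0
    for (dd in zlo:zhi) {
      crit[, , dd] <- rect_criterion_slice(matrix(astar[, , dd], h, w), rh, rw)
    }
  }
  out$size <- ph
  attr(out, "grid") <- grid
  attr(out, "criterion") <- critval
  out
}

#' Extract a single-slice square patch
#'
#' @param volume `(H, W, D)` array.
#' @param loc one row of the data.frame returned by
#'   [retrieve_roi_from_3d_image()] (0-based `slice`, `top`, `left`,
#'   `size`), or a list with those fields.
#' @return `(size, size)` matrix, values copied without resampling.
#' @export
extract_patch <- function(volume, loc) {
  dm <- dim(volume)
  ph <- if (!is.null(loc$size)) loc$size else 256L
  top <- loc$top + 1L
  left <- loc$left + 1L
  sl <- loc$slice + 1L
  if (top < 1L || left < 1L || sl < 1L || sl > dm[3] ||
      top + ph - 1L > dm[1] || left + ph - 1L > dm[2]) {
    stop("patch location out of bounds")
  }
  volume[top:(top + ph - 1L), left:(left + ph - 1L), sl]
}

#' Write patch locations to CSV
#'
#' @param locations data.frame from [retrieve_roi_from_3d_image()].
#' @param id volume identifier recorded in the first column.
#' @param path output CSV path.
#' @export
write_patch_locations <- function(locations, id, path) {
  df <- cbind(volume_id = id, locations)
  write_atomic(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
}
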
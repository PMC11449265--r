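# Seeded generator of tomosynthesis-like phantom volumes: smooth textured
# background plus tiny class-conditional lesions whose in-plane footprint is
# identical on every slice they span, with contrast decaying exponentially
# away from a focus slice -- the "visible from most slices with varying
# focus" structure of reconstructed stacks (not an ellipsoidal 3D object).

#' Phantom specification
#'
#' Defaults define the desk-scale study conditions used throughout the test
#' suite: 64 x 64 slices, 4-8 slices per stack, at most one lesion per class
#' of radius 2-2.5 px (so that lesion voxels always occupy under 1\% of the
#' volume), additive contrast 0.3-0.6 at the focus slice decaying with
#' scale `focus_spread` slices, benign lesions round, malignant lesions
#' spiculated (star polygon with 6-10 thin spikes whose pixel area matches
#' a disc of the same nominal radius but whose spicules reach twice as far
#' out).
#'
#' @param height,width slice size in pixels (>= 64).
#' @param slice_count_range integer interval for D, within `[2, 96]`.
#' @param background_texture_scale correlation length of the smooth
#'   background texture, pixels.
#' @param background_noise_sd sd of i.i.d. pixel noise, intensity units.
#' @param lesions_per_class_distribution probabilities of 0, 1, 2 lesions
#'   per class.
#' @param lesion_radius_range pixels; max must be <= min(height, width)/8.
#' @param focus_spread decay scale (slices) of lesion contrast away from
#'   its focus slice; >= 1.
#' @param lesion_contrast_range additive intensity at the focus slice.
#' @return validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64L, width = 64L,
                         slice_count_range = c(4L, 8L),
                         background_texture_scale = 8,
                         background_noise_sd = 0.02,
                         lesions_per_class_distribution = c(0.5, 0.5, 0),
                         lesion_radius_range = c(2, 2.5),
                         focus_spread = 3,
                         lesion_contrast_range = c(0.3, 0.6)) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               slice_count_range = as.integer(slice_count_range),
               background_texture_scale = background_texture_scale,
               background_noise_sd = background_noise_sd,
               lesions_per_class_distribution = lesions_per_class_distribution,
               lesion_radius_range = lesion_radius_range,
               focus_spread = focus_spread,
               lesion_contrast_range = lesion_contrast_range,
               benign_shape = "round", malignant_shape = "spiculated")
  stopifnot(spec$height >= 64L, spec$width >= 64L,
            length(spec$slice_count_range) == 2L,
            spec$slice_count_range[1] >= 2L, spec$slice_count_range[2] <= 96L,
            spec$slice_count_range[1] <= spec$slice_count_range[2],
            max(spec$lesion_radius_range) <= min(spec$height, spec$width) / 8,
            spec$focus_spread >= 1,
            all(spec$lesion_contrast_range > 0),
            length(spec$lesions_per_class_distribution) == 3L,
            abs(sum(spec$lesions_per_class_distribution) - 1) < 1e-8)
  class(spec) <- "phantom_spec"
  spec
}

# smooth per-slice background texture: coarse gaussian grid, bilinear upsample
smooth_texture <- function(h, w, scale, amplitude = 0.08) {
  gh <- max(2L, ceiling(h / scale) + 1L)
  gw <- max(2L, ceiling(w / scale) + 1L)
  g <- matrix(stats::rnorm(gh * gw), gh, gw)
  ri <- seq(1, gh, length.out = h)
  ci <- seq(1, gw, length.out = w)
  r0 <- pmin(floor(ri), gh - 1L); a <- ri - r0
  c0 <- pmin(floor(ci), gw - 1L); b <- ci - c0
  m00 <- g[r0, c0]; m10 <- g[r0 + 1L, c0]
  m01 <- g[r0, c0 + 1L]; m11 <- g[r0 + 1L, c0 + 1L]
  A <- matrix(a, h, w); B <- matrix(b, h, w, byrow = TRUE)
  up <- (1 - A) * (1 - B) * m00 + A * (1 - B) * m10 +
    (1 - A) * B * m01 + A * B * m11
  amplitude * up
}

# binary footprint of one lesion on the slice plane; for spiculated
# lesions `radius` is the core scale and the spicules reach 2 * radius,
# giving a pixel area comparable to a disc of the same nominal radius but a
# much wider spatial extent
lesion_reach <- function(radius, shape) {
  if (shape == "round") radius else 2 * radius
}

lesion_footprint <- function(h, w, cr, cc, radius, shape, n_spikes = 8L,
                             phase = 0) {
  pad <- ceiling(lesion_reach(radius, shape)) + 1L
  rows <- max(1L, floor(cr - pad)):min(h, ceiling(cr + pad))
  cols <- max(1L, floor(cc - pad)):min(w, ceiling(cc + pad))
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  dist <- sqrt(dr^2 + dc^2)
  if (shape == "round") {
    inside <- dist <= radius
  } else {
    theta <- atan2(dc, dr)
    # star polygon: core disc of 0.4 * radius with thin spicules out to
    # 2 * radius; the 4th-power lobe keeps the pixel area equal to a disc
    # of the same nominal radius
    lobe <- (0.5 + 0.5 * cos(n_spikes * (theta - phase)))^4
    inside <- dist <= radius * (0.4 + 1.6 * lobe)
  }
  list(rows = rows, cols = cols, inside = inside)
}

# draw lesion placements for one phantom (shared across views of a group).
# The per-class lesion counts are drawn once; the geometry draw is rejected
# and repeated if the total stamped footprint would reach 1% of a slice, so
# lesion voxels always stay below 1% of the volume (a single lesion cannot
# reach the budget, so this terminates).
sample_lesion_config <- function(spec, D) {
  counts <- vapply(1:2, function(ci) {
    sample(0:2, 1L, prob = spec$lesions_per_class_distribution)
  }, integer(1))
  budget <- 0.01 * spec$height * spec$width
  for (attempt in 1:100) {
    les <- draw_lesion_geometry(spec, D, counts)
    area <- sum(vapply(les, function(l) {
      shape <- if (l$class == 1L) spec$benign_shape else spec$malignant_shape
      sum(lesion_footprint(spec$height, spec$width, l$cr, l$cc, l$radius,
                           shape, l$n_spikes, l$phase)$inside)
    }, numeric(1)))
    if (area < budget) return(les)
  }
  stop("lesion geometry exceeded the 1% footprint budget after 100 draws; ",
       "spec radii are too large for ", spec$height, "x", spec$width)
}

draw_lesion_geometry <- function(spec, D, counts) {
  les <- list()
  existing <- NULL
  for (ci in 1:2) {
    n <- counts[ci]
    if (n == 0L) next
    shape <- if (ci == 1L) spec$benign_shape else spec$malignant_shape
    for (j in seq_len(n)) {
      radius <- stats::runif(1, spec$lesion_radius_range[1],
                             spec$lesion_radius_range[2])
      reach <- lesion_reach(radius, shape)
      placed <- FALSE
      for (trial in 1:100) {
        margin <- reach + 2
        cr <- stats::runif(1, margin, spec$height - margin)
        cc <- stats::runif(1, margin, spec$width - margin)
        ok <- TRUE
        if (!is.null(existing)) {
          dd <- sqrt((existing$cr - cr)^2 + (existing$cc - cc)^2)
          ok <- all(dd > existing$reach + reach + 2)
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) {
        stop("lesion placement failed non-overlap after 100 trials; ",
             "spec is too crowded (", spec$height, "x", spec$width,
             ", radius up to ", spec$lesion_radius_range[2], ")")
      }
      rec <- list(class = ci, cr = cr, cc = cc, radius = radius,
                  focus = sample.int(D, 1L),
                  contrast = stats::runif(1, spec$lesion_contrast_range[1],
                                          spec$lesion_contrast_range[2]),
                  n_spikes = sample(6:10, 1L),
                  phase = stats::runif(1, 0, 2 * pi))
      les[[length(les) + 1L]] <- rec
      existing <- rbind(existing,
                        data.frame(cr = cr, cc = cc, reach = reach))
    }
  }
  les
}

#' Generate one phantom volume
#'
#' Background is smooth per-slice texture plus i.i.d. noise around a base
#' level of 0.35; each lesion is a 2D shape stamped at a fixed (x, y) with
#' additive contrast `contrast * exp(-|d - focus| / focus_spread)` on every
#' slice of the stack (identical in-plane footprint on all slices, so the
#' mask marks the full spatial footprint on every slice); intensities are
#' clipped to `[0, 1]`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same spec and seed reproduce the volume
#'   bit-for-bit. `NULL` uses the current RNG state.
#' @param D optional fixed slice count (default: drawn from the spec range).
#' @param lesion_config optional precomputed lesion list (used to render a
#'   second "view" of the same subject); by default drawn from the spec.
#' @return list of class `phantom_sample`: `volume` `(H, W, D)` in
#'   `[0, 1]`, `labels` `c(y_b, y_m)`, `masks` `(H, W, D, 2)` binary, and
#'   `metadata` (spec, seed, lesion records).
#' @export
generate_phantom <- function(spec, seed = NULL, D = NULL,
                             lesion_config = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    if (is.null(D)) {
      D <- sample(spec$slice_count_range[1]:spec$slice_count_range[2], 1L)
    }
    h <- spec$height; w <- spec$width
    vol <- array(0.35, c(h, w, D))
    for (d in seq_len(D)) {
      vol[, , d] <- vol[, , d] +
        smooth_texture(h, w, spec$background_texture_scale) +
        matrix(stats::rnorm(h * w, sd = spec$background_noise_sd), h, w)
    }
    if (is.null(lesion_config)) lesion_config <- sample_lesion_config(spec, D)
    masks <- array(0L, c(h, w, D, 2L))
    for (les in lesion_config) {
      shape <- if (les$class == 1L) spec$benign_shape else spec$malignant_shape
      fp <- lesion_footprint(h, w, les$cr, les$cc, les$radius, shape,
                             les$n_spikes, les$phase)
      focus <- min(les$focus, D)
      for (d in seq_len(D)) {
        amp <- les$contrast * exp(-abs(d - focus) / spec$focus_spread)
        plane <- vol[fp$rows, fp$cols, d]
        plane[fp$inside] <- plane[fp$inside] + amp
        vol[fp$rows, fp$cols, d] <- plane
        mp <- masks[fp$rows, fp$cols, d, les$class]
        mp[fp$inside] <- 1L
        masks[fp$rows, fp$cols, d, les$class] <- mp
      }
    }
    vol <- clamp(vol, 0, 1)
    labels <- c(y_b = as.integer(any(masks[, , , 1] > 0)),
                y_m = as.integer(any(masks[, , , 2] > 0)))
    structure(list(volume = vol, labels = labels, masks = masks,
                   metadata = list(spec = spec, seed = seed,
                                   lesions = lesion_config)),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` volumes (and their ground-truth masks) plus a CSV manifest.
#' Per-sample seeds are derived deterministically from the master seed, so
#' regeneration with the same arguments is byte-identical. With
#' `views_per_group = 2`, consecutive samples share one lesion layout
#' rendered with independent noise and slice counts, emulating two views of
#' the same subject for group-averaged evaluation.
#'
#' @param n number of samples (>= 1).
#' @param spec a [phantom_spec()].
#' @param seed master integer seed.
#' @param out_dir output directory; refused if it exists non-empty unless
#'   `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty directory.
#' @param format `"nifti"` (.nii.gz) or `"tiff"` (multi-page).
#' @param views_per_group 1 or 2 rendered views per subject.
#' @param split named fractions for train/val/test assignment (by group).
#' @return the manifest data.frame (also written to
#'   `file.path(out_dir, "manifest.csv")`) with columns id, volume_path,
#'   mask_path, y_b, y_m, D, group_id, split.
#' @export
generate_dataset <- function(n, spec, seed, out_dir, overwrite = FALSE,
                             format = c("nifti", "tiff"),
                             views_per_group = 1L,
                             split = c(train = 0.7, val = 0.15, test = 0.15)) {
  stopifnot(n >= 1)
  format <- match.arg(format)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop("out_dir exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "nifti") ".nii.gz" else ".tif"
  rows <- vector("list", n)
  group_of <- ceiling(seq_len(n) / views_per_group)
  n_groups <- max(group_of)
  split_of <- with_seed(derive_seed(seed, 0L), {
    sample(rep(names(split), times = round_half_up(split * n_groups) + 1L)[seq_len(n_groups)])
  })
  lesion_cache <- list()
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    gid <- group_of[i]
    lc <- lesion_cache[[as.character(gid)]]
    ph <- generate_phantom(spec, seed = si, lesion_config = lc)
    if (is.null(lc)) lesion_cache[[as.character(gid)]] <- ph$metadata$lesions
    id <- sprintf("phantom_%04d", i)
    vp <- file.path(out_dir, paste0(id, ext))
    mp <- file.path(out_dir, paste0(id, "_mask", ext))
    write_volume(ph$volume, vp)
    msk <- ph$masks
    if (format == "tiff") {
      # TIFF has no 4th axis: store the two class channels as D extra pages
      msk <- array(msk, c(dim(msk)[1:2], dim(msk)[3] * 2L))
    }
    write_volume(msk, mp)
    rows[[i]] <- data.frame(id = id, volume_path = basename(vp),
                            mask_path = basename(mp),
                            y_b = ph$labels[["y_b"]], y_m = ph$labels[["y_m"]],
                            D = dim(ph$volume)[3], group_id = gid,
                            split = split_of[gid])
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
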
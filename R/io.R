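# Volume and manifest I/O. Volumes are plain (H, W, D) arrays in [0, 1]
# (4D mask stacks are passed through unchanged); readers never mutate files
# and writers go through a temp-file + rename.

#' Read a volume from NIfTI or multi-page TIFF
#'
#' Axis order is normalized to `(H, W, D)` with a single-page 2D file
#' becoming `D = 1`; integer-typed data are rescaled to `[0, 1]` by the
#' per-volume maximum representable value of the observed range.
#'
#' @param path a `.nii`, `.nii.gz`, `.tif` or `.tiff` file.
#' @param id optional identifier stored as an attribute.
#' @return numeric array `(H, W, D)` (or `(H, W, D, C)` for 4D NIfTI) with
#'   attributes `id` and, when available, `spacing`.
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read volume, file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    spacing <- attr(RNifti::niftiHeader(img), "pixdim")
  } else if (grepl("\\.tiff?$", lower)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p[, , 1] else p   # drop extra channels
    })
    vals <- array(unlist(pages, use.names = FALSE),
                  c(dim(pages[[1]]), length(pages)))
    spacing <- NULL
  } else {
    stop("unsupported volume format: ", path)
  }
  if (length(dim(vals)) == 2L) vals <- array(vals, c(dim(vals), 1L))
  if (dim(vals)[3] == 0L) stop("volume has zero slices: ", path)
  if (is.integer(vals) || max(abs(vals - round(vals))) == 0 && max(vals) > 1) {
    vals <- vals / max(vals, 1)
  }
  storage.mode(vals) <- "double"
  if (!all(is.finite(vals))) stop("volume contains non-finite values: ", path)
  attr(vals, "id") <- id %||% sub("\\.(nii(\\.gz)?|tiff?)$", "",
                                  basename(lower))
  attr(vals, "spacing") <- spacing
  vals
}

#' Write a volume to NIfTI or multi-page TIFF
#'
#' @param values numeric array, `(H, W, D)` or `(H, W, D, C)` (the latter
#'   NIfTI only).
#' @param path destination; format chosen by extension. Writing is atomic
#'   (temp file + rename).
#' @export
write_volume <- function(values, path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    # RNifti infers gzip from the final name, so write under a temp name
    # with the same extension in the same directory
    tmp <- file.path(dirname(path), paste0(".tmp", Sys.getpid(), basename(path)))
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    RNifti::writeNifti(RNifti::asNifti(values), tmp)
    if (!file.rename(tmp, path)) {
      file.copy(tmp, path, overwrite = TRUE)
      unlink(tmp)
    }
  } else if (grepl("\\.tiff?$", lower)) {
    stopifnot(length(dim(values)) == 3L)
    pages <- lapply(seq_len(dim(values)[3]), function(d) {
      clamp(values[, , d], 0, 1)
    })
    write_atomic(path, function(tmp) {
      tiff::writeTIFF(pages, tmp, bits.per.sample = 16L)
    })
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

manifest_columns <- c("id", "volume_path", "mask_path", "y_b", "y_m", "D",
                      "group_id", "split")

#' Read / write a dataset manifest
#'
#' The manifest is a CSV with columns `id, volume_path, mask_path, y_b,
#' y_m, D, group_id, split` (paths relative to the manifest's directory;
#' `mask_path` may be empty; `split` one of train/val/test).
#'
#' @param path CSV file.
#' @return data.frame with the columns above plus attribute `dir` (the
#'   manifest's directory, for resolving relative paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(manifest_columns, c("mask_path", "split")),
                     names(df))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(df$y_b %in% 0:1) || !all(df$y_m %in% 0:1)) {
    stop("manifest labels must be in {0, 1}")
  }
  if (!is.null(df$split) && !all(df$split %in% c("train", "val", "test"))) {
    stop("manifest split values must be train/val/test")
  }
  attr(df, "dir") <- dirname(normalizePath(path))
  df
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write_atomic(path, function(tmp) {
    utils::write.csv(manifest, tmp, row.names = FALSE)
  })
  invisible(path)
}

# Load manifest rows into in-memory samples: list(volume, labels, mask?, id)
load_manifest_samples <- function(manifest, split = NULL, dir = NULL,
                                  with_masks = FALSE) {
  dir <- dir %||% attr(manifest, "dir") %||% "."
  rows <- if (!is.null(split)) manifest[manifest$split %in% split, ] else manifest
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    vol <- read_volume(file.path(dir, r$volume_path), id = r$id)
    s <- list(volume = vol, labels = c(y_b = r$y_b, y_m = r$y_m),
              id = r$id, group_id = r$group_id)
    if (with_masks && !is.null(r$mask_path) && nzchar(r$mask_path)) {
      m <- read_volume(file.path(dir, r$mask_path), id = paste0(r$id, "_mask"))
      if (length(dim(m)) == 3L) {
        D <- dim(vol)[3]
        # TIFF masks store the two class channels as D extra pages
        m <- if (dim(m)[3] == 2L * D) array(m, c(dim(m)[1:2], D, 2L))
             else array(m, c(dim(m), 1L))
      }
      s$masks <- m
    }
    s
  })
}

#' Export saliency maps as NIfTI volumes
#'
#' Writes one file per class, aligned to the input grid via the downsample
#' factor (stored in the NIfTI pixdim as the voxel size).
#'
#' @param saliency `(h, w, D, 2)` array.
#' @param prefix output path prefix; files `<prefix>_benign.nii.gz` and
#'   `<prefix>_malignant.nii.gz` are created.
#' @param downsample integer scale between saliency grid and image grid.
#' @return invisibly, the two file paths.
#' @export
export_saliency <- function(saliency, prefix, downsample = 16L) {
  dm <- dim(saliency)
  stopifnot(length(dm) == 4L, dm[4] == 2L)
  paths <- c(paste0(prefix, "_benign.nii.gz"),
             paste0(prefix, "_malignant.nii.gz"))
  for (k in 1:2) {
    img <- RNifti::asNifti(array(saliency[, , , k], dm[1:3]))
    img <- RNifti::`pixdim<-`(img, c(downsample, downsample, 1))
    tmp <- file.path(dirname(paths[k]),
                     paste0(".tmp", Sys.getpid(), basename(paths[k])))
    RNifti::writeNifti(img, tmp)
    file.rename(tmp, paths[k])
  }
  invisible(paths)
}
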
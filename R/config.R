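#' Model and training configuration
#'
#' Builds a validated configuration for the two-stage classifier. Two
#' profiles are provided: `"paper"` carries the full-scale defaults used
#' with tomosynthesis stacks (256-pixel patches, K = 8 retrieved patches,
#' slice-suppression half-width zeta = 10, inputs around 2116 x 1339 x D),
#' while `"desk"` scales every spatial quantity down for CPU-sized
#' experiments on 64 x 64 phantoms (32-pixel patches, K = 4) and uses a
#' learning rate suited to training the compact backbone from scratch.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... named overrides of individual fields (unknown names are an
#'   error).
#'
#' @details Fields (units in brackets):
#' * `t`: top-t\% pooling percentage, referenced to the area of a single
#'   slice of the saliency map, so the pooled count does not depend on the
#'   slice count \[percent of one slice\].
#' * `omega`: constant used to initialize every weight of the 1x1
#'   segmentation layer (bias starts at zero).
#' * `K`: number of patches retrieved per volume.
#' * `zeta`: slice-suppression / slice-sampling half-width \[slices\].
#' * `patch_size`: side of the square patches \[pixels\].
#' * `backbone_width`: channel count of the global per-slice encoder
#'   (must be divisible by 8 for group normalization).
#' * `backbone_downsample`: total spatial downsampling of the global
#'   encoder (16 or 32).
#' * `local_width`: channel count of the patch encoder.
#' * `S`, `L`: patch-feature dimension and attention dimension.
#' * `lr`, `beta`: Adam learning rate and saliency L1 weight.
#' * `epochs`, `patience`: training epoch cap and early-stopping patience.
#' * `grad_accum`: volumes per optimizer update (effective batch size).
#' * `tta_count`: augmented passes averaged at test time.
#' * `max_shift` \[pixels\] and `scale_jitter` (relative) for augmentation.
#' * `nonlinearity`: `"relu_tanh"` (default) or `"sigmoid"` for the
#'   saliency nonlinearity (the latter only for A/B comparisons).
#' * `local_norm`: `"group"` (default) or `"batch"` normalization in the
#'   patch encoder; group norm is batch-size independent, batch norm pools
#'   statistics over the patches of each step.
#' @return a list of class `gmic3d_config`.
#' @export
#' @examples
#' cfg <- gmic3d_config("desk", K = 2)
#' cfg$K
gmic3d_config <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(
      t = 100, omega = 0.003, K = 8L, zeta = 10L, patch_size = 256L,
      backbone_width = 16L, backbone_downsample = 16L, local_width = 32L,
      S = 512L, L = 128L, lr = 1e-5, beta = 3e-6, epochs = 40L,
      patience = 15L, grad_accum = 4L, tta_count = 10L, max_shift = 100L,
      scale_jitter = 0.05, nonlinearity = "relu_tanh", local_norm = "group"
    )
  } else {
    list(
      t = 25, omega = 0.003, K = 4L, zeta = 2L, patch_size = 32L,
      backbone_width = 16L, backbone_downsample = 8L, local_width = 16L,
      S = 512L, L = 128L, lr = 2e-3, beta = 1e-5, epochs = 40L,
      patience = 15L, grad_accum = 4L, tta_count = 10L, max_shift = 2L,
      scale_jitter = 0.03, nonlinearity = "relu_tanh", local_norm = "group"
    )
  }
  cfg$profile <- profile
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

#' @rdname gmic3d_config
#' @param cfg a configuration list.
#' @export
validate_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  chk(is.numeric(cfg$t) && cfg$t > 0, "t")
  chk(is.numeric(cfg$omega) && cfg$omega > 0, "omega")
  chk(is.numeric(cfg$K) && cfg$K >= 1, "K")
  chk(is.numeric(cfg$zeta) && cfg$zeta >= 0, "zeta")
  chk(is.numeric(cfg$patch_size) && cfg$patch_size >= 4, "patch_size")
  chk(is.numeric(cfg$backbone_width) && cfg$backbone_width %% 8 == 0,
      "backbone_width")
  chk(cfg$backbone_downsample %in% c(8L, 16L, 32L), "backbone_downsample")
  chk(is.numeric(cfg$lr) && cfg$lr > 0, "lr")
  chk(is.numeric(cfg$beta) && cfg$beta >= 0, "beta")
  chk(is.numeric(cfg$tta_count) && cfg$tta_count >= 1, "tta_count")
  chk(is.numeric(cfg$max_shift) && cfg$max_shift >= 0, "max_shift")
  chk(cfg$nonlinearity %in% c("relu_tanh", "sigmoid"), "nonlinearity")
  chk(cfg$local_norm %in% c("group", "batch"), "local_norm")
  if (length(bad)) {
    stop("invalid config values for keys: ", paste(bad, collapse = ", "))
  }
  ints <- c("K", "zeta", "patch_size", "backbone_width",
            "backbone_downsample", "local_width", "S", "L", "epochs",
            "patience", "grad_accum", "tta_count", "max_shift")
  cfg[ints] <- lapply(cfg[ints], as.integer)
  structure(cfg, class = "gmic3d_config")
}

#' Read / write configuration files
#'
#' YAML round trip for [gmic3d_config()]. Unknown keys are rejected and all
#' omitted keys are filled with the profile defaults; the fully resolved
#' configuration is what is returned (and what [write_config()] dumps), so a
#' dumped file reloads to an identical object.
#'
#' @param path a YAML file. May contain a `profile` key plus any subset of
#'   the fields documented in [gmic3d_config()].
#' @return the validated configuration.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  profile <- raw$profile %||% "desk"
  raw$profile <- NULL
  do.call(gmic3d_config, c(list(profile = profile), raw))
}

#' @rdname load_config
#' @param cfg a `gmic3d_config` object.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  write_atomic(path, function(tmp) yaml::write_yaml(x, tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
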
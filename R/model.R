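# Full two-stage forward pass, loss, augmentation/TTA, and the backward
# pass used by the training loop. The patch selection is a non-differentiable
# crop: no gradient flows from the local loss into the global network through
# patch coordinates; each module is trained by its own BCE term.

BCE_EPS <- 1e-7

#' Initialize an untrained model
#'
#' Builds the global per-slice encoder, the constant-initialized 1x1
#' segmentation layer (all weights `omega`, bias zero), the patch encoder,
#' the gated-attention parameters and the local head.
#'
#' @param config a [gmic3d_config()].
#' @param seed integer seed for the random initialization.
#' @return object of class `gmic3d` (unfitted).
#' @export
gmic3d_init <- function(config = gmic3d_config(), seed = 1L) {
  config <- validate_config(config)
  params <- with_seed(seed, {
    seg <- init_segmentation_layer(config$backbone_width, config$omega)
    c(init_global_backbone(config$backbone_width),
      list(seg_W = seg$weights, seg_b = seg$bias),
      init_patch_encoder(config$local_width, config$S),
      list(
        att_V = matrix(stats::rnorm(config$L * config$S,
                                    sd = sqrt(1 / config$S)),
                       config$L, config$S),
        att_U = matrix(stats::rnorm(config$L * config$S,
                                    sd = sqrt(1 / config$S)),
                       config$L, config$S),
        att_w = matrix(stats::rnorm(config$L, sd = sqrt(1 / config$L)),
                       config$L, 1L),
        head_W = matrix(0, config$S, 2L)
      ))
  })
  structure(list(params = params, buffers = init_encoder_buffers(config$local_width),
                 config = config, fitted = FALSE, seed = seed),
            class = "gmic3d")
}

# Full forward pass. With keep_cache = TRUE all layer caches are retained for
# the backward pass; `training` enables slice resampling in retrieval and
# batch statistics in the patch encoder (and updates the returned buffers).
gmic3d_forward_full <- function(model, volume, training = FALSE,
                                keep_cache = FALSE) {
  cfg <- model$config
  P <- model$params
  dm <- dim(volume)
  bw <- global_backbone_forward(volume_to_tensor(volume), P,
                                cfg$backbone_downsample)
  feat_mat <- bw$out$mat                      # (D*h*w, c), slice-major
  h <- bw$out$h; w <- bw$out$w; D <- bw$out$n
  logits <- sweep(feat_mat %*% P$seg_W, 2L, P$seg_b, "+")
  A <- if (cfg$nonlinearity == "sigmoid") sigmoid(logits) else relu_tanh(logits)
  saliency <- array(A, c(h, w, D, 2L))
  n_pool <- top_t_count(h, w, D, cfg$t)
  pool <- lapply(1:2, function(k) {
    v <- A[, k]
    idx <- order(v, decreasing = TRUE)[seq_len(n_pool)]
    list(idx = idx, p = mean(v[idx]))
  })
  p_global <- c(benign = pool[[1]]$p, malignant = pool[[2]]$p)

  locs <- retrieve_roi_from_3d_image(saliency, cfg, dm, training = training)
  patches <- lapply(seq_len(nrow(locs)), function(k) {
    extract_patch(volume, locs[k, ])
  })
  enc <- patch_encoder_forward(patches_to_tensor(patches), P, model$buffers,
                               training = training, norm = cfg$local_norm)
  att <- attention_forward(enc$out, P)
  z <- as.vector(crossprod(enc$out, att$alpha))
  logit_local <- as.vector(z %*% P$head_W)
  p_local <- sigmoid(logit_local)
  names(p_local) <- c("benign", "malignant")
  p_final <- (p_global + p_local) / 2

  out <- list(p_global = p_global, p_local = p_local, p_final = p_final,
              saliency = saliency, locations = locs, alpha = att$alpha,
              buffers = enc$buffers)
  if (keep_cache) {
    out$cache <- list(bw = bw, logits = logits, A = A, pool = pool,
                      n_pool = n_pool, enc = enc, att = att, z = z,
                      logit_local = logit_local, p_local_raw = p_local,
                      h = h, w = w, D = D)
  }
  out
}

#' Run the full model on one volume
#'
#' @param model a `gmic3d` model.
#' @param volume `(H, W, D)` array (H, W at least `patch_size`).
#' @param training logical; enables the training-time stochastic slice
#'   resampling in retrieval and batch statistics in the patch encoder.
#' @return list with `p_global`, `p_local`, `p_final` (named probability
#'   pairs; `p_final` is their arithmetic mean), `saliency` `(h, w, D, 2)`,
#'   `locations` (K patch locations) and `alpha` (K attention weights).
#' @export
gmic3d_forward <- function(model, volume, training = FALSE) {
  out <- gmic3d_forward_full(model, volume, training = training)
  out$buffers <- NULL
  out
}

#' Saliency L1 (sparsity) penalty
#'
#' Sum of absolute saliency values of one class plane; since saliency is
#' non-negative this is the plain sum.
#'
#' @param class_plane `(h, w, D)` array.
#' @return non-negative scalar.
#' @export
saliency_l1 <- function(class_plane) sum(abs(class_plane))

bce <- function(y, p) {
  p <- clamp(p, BCE_EPS, 1 - BCE_EPS)
  -y * log(p) - (1 - y) * log(1 - p)
}

#' Training loss
#'
#' Per class (benign, malignant): BCE of the local prediction plus BCE of
#' the global prediction -- computed separately, not the BCE of their
#' average, so neither module can hide behind the other -- plus `beta`
#' times the saliency L1 penalty.
#'
#' @param y length-2 0/1 labels `(y_b, y_m)`.
#' @param output result of [gmic3d_forward()].
#' @param beta saliency regularization weight, >= 0.
#' @return non-negative scalar.
#' @export
total_loss <- function(y, output, beta) {
  if (!all(y %in% c(0, 1))) stop("labels must be in {0, 1}")
  dm <- dim(output$saliency)
  loss <- 0
  for (k in 1:2) {
    loss <- loss + bce(y[k], output$p_local[[k]]) +
      bce(y[k], output$p_global[[k]]) +
      beta * saliency_l1(array(output$saliency[, , , k], dm[1:3]))
  }
  loss
}

# ---- augmentation -------------------------------------------------------------

# bilinear resample of one slice under shift (dr, dc) and scale s about the
# image center; zeros outside
warp_slice <- function(plane, dr, dc, s) {
  h <- nrow(plane); w <- ncol(plane)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  sr <- cy + (seq_len(h) - dr - cy) / s
  sc <- cx + (seq_len(w) - dc - cx) / s
  r0 <- floor(sr); a <- sr - r0
  c0 <- floor(sc); b <- sc - c0
  gp <- function(ri, ci) {
    ok_r <- ri >= 1 & ri <= h
    ok_c <- ci >= 1 & ci <= w
    m <- matrix(0, h, w)
    if (any(ok_r) && any(ok_c)) {
      m[ok_r, ok_c] <- plane[ri[ok_r], ci[ok_c]]
    }
    m
  }
  A <- matrix(a, h, w); B <- matrix(b, h, w, byrow = TRUE)
  (1 - A) * (1 - B) * gp(r0, c0) + A * (1 - B) * gp(r0 + 1, c0) +
    (1 - A) * B * gp(r0, c0 + 1) + A * B * gp(r0 + 1, c0 + 1)
}

#' Random shift-and-resize augmentation
#'
#' Samples an integer translation up to `max_shift` pixels in each direction
#' and a mild rescale in `1 +/- scale_jitter`, and applies the identical
#' transform to every slice (zero padding). `max_shift = 0` and
#' `scale_jitter = 0` give the identity.
#'
#' @param volume `(H, W, D)` array.
#' @param max_shift maximum |shift| in pixels.
#' @param scale_jitter relative scale half-range (0 disables rescaling).
#' @return augmented volume, same shape; attributes `shift` and `scale`
#'   record the transform.
#' @export
augment_volume <- function(volume, max_shift = 0L, scale_jitter = 0) {
  dr <- if (max_shift > 0) sample(-max_shift:max_shift, 1L) else 0L
  dc <- if (max_shift > 0) sample(-max_shift:max_shift, 1L) else 0L
  s <- if (scale_jitter > 0) stats::runif(1, 1 - scale_jitter, 1 + scale_jitter) else 1
  if (dr == 0L && dc == 0L && s == 1) {
    attr(volume, "shift") <- c(0L, 0L); attr(volume, "scale") <- 1
    return(volume)
  }
  out <- volume
  for (d in seq_len(dim(volume)[3])) {
    out[, , d] <- warp_slice(volume[, , d], dr, dc, s)
  }
  attr(out, "shift") <- c(dr, dc); attr(out, "scale") <- s
  out
}

#' Test-time augmentation
#'
#' Averages `p_final` over `n_aug` randomly augmented forward passes.
#'
#' @param model a `gmic3d` model.
#' @param volume `(H, W, D)` array.
#' @param n_aug number of augmented passes (>= 1).
#' @return named probability pair; lies within the range of the individual
#'   predictions.
#' @export
tta_predict <- function(model, volume, n_aug = NULL) {
  cfg <- model$config
  n_aug <- n_aug %||% cfg$tta_count
  stopifnot(n_aug >= 1)
  ps <- vapply(seq_len(n_aug), function(i) {
    v <- augment_volume(volume, cfg$max_shift, cfg$scale_jitter)
    gmic3d_forward(model, v)$p_final
  }, numeric(2))
  p <- rowMeans(ps)
  names(p) <- c("benign", "malignant")
  p
}

# ---- backward pass (one volume) -----------------------------------------------

# returns list(loss, grads, buffers)
gmic3d_train_step <- function(model, volume, y, training = TRUE) {
  cfg <- model$config
  P <- model$params
  fw <- gmic3d_forward_full(model, volume, training = training,
                            keep_cache = TRUE)
  cache <- fw$cache
  loss <- total_loss(y, fw, cfg$beta)

  grads <- list()

  # ---- local path
  p_loc <- cache$p_local_raw
  dlogit_local <- unname(p_loc - y)                     # BCE-with-logits
  grads$head_W <- cache$z %*% t(dlogit_local)           # S x 2
  dz <- as.vector(P$head_W %*% dlogit_local)            # S
  feats <- cache$enc$out
  dalpha <- as.vector(feats %*% dz)                     # K
  dfeats <- cache$att$alpha %*% t(dz)                   # K x S
  ab <- attention_backward(dalpha, cache$att$cache, P)
  grads$att_w <- ab$att_w; grads$att_V <- ab$att_V; grads$att_U <- ab$att_U
  dfeats <- dfeats + ab$dfeats
  genc <- patch_encoder_backward(dfeats, cache$enc$cache)
  grads <- c(grads, genc)

  # ---- global path: BCE through top-n pooling + L1 on all entries
  dA <- matrix(cfg$beta, nrow(cache$A), 2L)             # d(L1)/dA = beta
  for (k in 1:2) {
    p <- clamp(cache$pool[[k]]$p, BCE_EPS, 1 - BCE_EPS)
    dL_dp <- (p - y[k]) / (p * (1 - p))
    idx <- cache$pool[[k]]$idx
    dA[idx, k] <- dA[idx, k] + dL_dp / cache$n_pool
  }
  dlogits <- if (cfg$nonlinearity == "sigmoid") {
    dA * cache$A * (1 - cache$A)
  } else {
    dA * (cache$logits > 0) * (1 - tanh(cache$logits)^2)
  }
  grads$seg_W <- crossprod(cache$bw$out$mat, dlogits)
  grads$seg_b <- colSums(dlogits)
  dfeat <- tensor_new(dlogits %*% t(P$seg_W), cache$h, cache$w, cache$D)
  gback <- global_backbone_backward(dfeat, cache$bw$cache)
  grads <- c(grads, gback)

  list(loss = loss, grads = grads, buffers = fw$buffers,
       p_final = fw$p_final)
}
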
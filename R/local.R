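# Local module: patch encoder, gated-attention aggregation over the K
# retrieved patches, and the local prediction head.

# Compact residual patch encoder: conv5x5/2 -> norm -> ReLU -> conv3x3/2 ->
# norm -> ReLU -> residual block -> global average pool -> linear to S ->
# ReLU. The normalization is group norm (8 groups) by default: in a
# single-device run the encoder's "batch" is only the K patches of one
# volume, which is too small and too correlated for useful batch
# statistics. `local_norm = "batch"` switches to batch normalization over
# the union of patches in the step (the single-device equivalent of a
# synchronized batch-normalization layer), with running statistics for
# evaluation; in either mode eval features are deterministic and
# independent of the other patches in the batch.

init_patch_encoder <- function(width, S, seed = NULL) {
  with_seed(seed, {
    list(
      l_conv1_W = init_conv_w(5L, 5L, 1L, width), l_conv1_b = rep(0, width),
      l_bn1_g = rep(1, width), l_bn1_b = rep(0, width),
      l_conv2_W = init_conv_w(3L, 3L, width, width), l_conv2_b = rep(0, width),
      l_bn2_g = rep(1, width), l_bn2_b = rep(0, width),
      l_conv3_W = init_conv_w(3L, 3L, width, width), l_conv3_b = rep(0, width),
      l_bn3_g = rep(1, width), l_bn3_b = rep(0, width),
      l_conv4_W = init_conv_w(3L, 3L, width, width), l_conv4_b = rep(0, width),
      l_bn4_g = rep(1, width), l_bn4_b = rep(0, width),
      l_fc_W = matrix(stats::rnorm(width * S, sd = sqrt(2 / width)), width, S),
      l_fc_b = rep(0, S)
    )
  })
}

init_encoder_buffers <- function(width) {
  one <- function() list(mean = rep(0, width), var = rep(1, width))
  list(bn1 = one(), bn2 = one(), bn3 = one(), bn4 = one())
}

# normalization dispatch: "group" has no state; "batch" carries running stats
enc_norm_forward <- function(x, gamma, beta, running, training, type) {
  if (type == "batch") {
    batch_norm_forward(x, gamma, beta, running, training)
  } else {
    out <- group_norm_forward(x, gamma, beta)
    out$running <- running
    out$cache$gn <- TRUE
    out
  }
}

enc_norm_backward <- function(dout, cache) {
  if (isTRUE(cache$gn)) group_norm_backward(dout, cache)
  else batch_norm_backward(dout, cache)
}

patch_encoder_forward <- function(x, P, buffers, training = FALSE,
                                  norm = "group") {
  c1 <- conv2d_forward(x, P$l_conv1_W, P$l_conv1_b, stride = 2L, pad = 2L)
  b1 <- enc_norm_forward(c1$out, P$l_bn1_g, P$l_bn1_b, buffers$bn1, training, norm)
  r1 <- relu_forward(b1$out)
  c2 <- conv2d_forward(r1$out, P$l_conv2_W, P$l_conv2_b, stride = 2L, pad = 1L)
  b2 <- enc_norm_forward(c2$out, P$l_bn2_g, P$l_bn2_b, buffers$bn2, training, norm)
  r2 <- relu_forward(b2$out)
  c3 <- conv2d_forward(r2$out, P$l_conv3_W, P$l_conv3_b, stride = 1L, pad = 1L)
  b3 <- enc_norm_forward(c3$out, P$l_bn3_g, P$l_bn3_b, buffers$bn3, training, norm)
  r3 <- relu_forward(b3$out)
  c4 <- conv2d_forward(r3$out, P$l_conv4_W, P$l_conv4_b, stride = 1L, pad = 1L)
  b4 <- enc_norm_forward(c4$out, P$l_bn4_g, P$l_bn4_b, buffers$bn4, training, norm)
  res <- tensor_new(b4$out$mat + r2$out$mat, b4$out$h, b4$out$w, b4$out$n)
  r4 <- relu_forward(res)
  gp <- gap_forward(r4$out)
  fc <- linear_forward(gp$out, P$l_fc_W, P$l_fc_b)
  fmask <- fc$out > 0
  feats <- fc$out * fmask
  buffers$bn1 <- b1$running; buffers$bn2 <- b2$running
  buffers$bn3 <- b3$running; buffers$bn4 <- b4$running
  list(out = feats, buffers = buffers,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2,
                    c3 = c3, b3 = b3, r3 = r3, c4 = c4, b4 = b4, r4 = r4,
                    gp = gp, fc = fc, fmask = fmask))
}

patch_encoder_backward <- function(dfeats, cache) {
  g <- list()
  dfc <- dfeats * cache$fmask
  bl <- linear_backward(dfc, cache$fc$cache)
  g$l_fc_W <- bl$dW; g$l_fc_b <- bl$db
  d <- gap_backward(bl$dx, cache$gp$cache)
  d <- relu_backward(d, cache$r4$cache)
  dskip <- d
  bb4 <- enc_norm_backward(d, cache$b4$cache)
  g$l_bn4_g <- bb4$dgamma; g$l_bn4_b <- bb4$dbeta
  bc4 <- conv2d_backward(bb4$dx, cache$c4$cache)
  g$l_conv4_W <- bc4$dW; g$l_conv4_b <- bc4$db
  d <- relu_backward(bc4$dx, cache$r3$cache)
  bb3 <- enc_norm_backward(d, cache$b3$cache)
  g$l_bn3_g <- bb3$dgamma; g$l_bn3_b <- bb3$dbeta
  bc3 <- conv2d_backward(bb3$dx, cache$c3$cache)
  g$l_conv3_W <- bc3$dW; g$l_conv3_b <- bc3$db
  d <- tensor_new(bc3$dx$mat + dskip$mat, dskip$h, dskip$w, dskip$n)
  d <- relu_backward(d, cache$r2$cache)
  bb2 <- enc_norm_backward(d, cache$b2$cache)
  g$l_bn2_g <- bb2$dgamma; g$l_bn2_b <- bb2$dbeta
  bc2 <- conv2d_backward(bb2$dx, cache$c2$cache)
  g$l_conv2_W <- bc2$dW; g$l_conv2_b <- bc2$db
  d <- relu_backward(bc2$dx, cache$r1$cache)
  bb1 <- enc_norm_backward(d, cache$b1$cache)
  g$l_bn1_g <- bb1$dgamma; g$l_bn1_b <- bb1$dbeta
  bc1 <- conv2d_backward(bb1$dx, cache$c1$cache, need_dx = FALSE)
  g$l_conv1_W <- bc1$dW; g$l_conv1_b <- bc1$db
  g
}

# patches: list of (p, p) matrices -> tensor with n = K
patches_to_tensor <- function(patches) {
  p <- nrow(patches[[1]])
  mat <- matrix(unlist(lapply(patches, as.vector), use.names = FALSE), ncol = 1L)
  tensor_new(mat, p, ncol(patches[[1]]), length(patches))
}

#' Encode patches into feature vectors
#'
#' Runs the patch encoder in evaluation mode (frozen batch statistics), so
#' each patch's feature vector is deterministic and independent of the other
#' patches in the batch.
#'
#' @param patches a single `(p, p)` matrix or a list of them (all the same
#'   size, matching `config$patch_size`).
#' @param model a `gmic3d` model.
#' @return `(K, S)` matrix of feature vectors (S = 512 by default).
#' @export
encode_patch <- function(patches, model) {
  if (is.matrix(patches)) patches <- list(patches)
  p <- model$config$patch_size
  ok <- vapply(patches, function(x) is.matrix(x) && all(dim(x) == p) &&
                 all(is.finite(x)), logical(1))
  if (!all(ok)) stop("patches must be finite ", p, "x", p, " matrices")
  fw <- patch_encoder_forward(patches_to_tensor(patches), model$params,
                              model$buffers, training = FALSE,
                              norm = model$config$local_norm)
  fw$out
}

# ---- gated attention ----------------------------------------------------------

attention_forward <- function(feats, P) {
  Tm <- tanh(feats %*% t(P$att_V))      # K x L
  Sm <- sigmoid(feats %*% t(P$att_U))   # K x L
  G <- Tm * Sm
  scores <- as.vector(G %*% P$att_w)    # K
  alpha <- softmax_vec(scores)
  list(alpha = alpha,
       cache = list(feats = feats, Tm = Tm, Sm = Sm, G = G, alpha = alpha))
}

attention_backward <- function(dalpha, cache, P) {
  alpha <- cache$alpha
  ds <- alpha * (dalpha - sum(alpha * dalpha))   # softmax backward
  dw <- crossprod(cache$G, ds)                   # L x 1
  dG <- ds %*% t(P$att_w)                        # K x L
  dT <- dG * cache$Sm
  dS <- dG * cache$Tm
  dpreT <- dT * (1 - cache$Tm^2)
  dpreS <- dS * cache$Sm * (1 - cache$Sm)
  dV <- crossprod(dpreT, cache$feats)            # L x S
  dU <- crossprod(dpreS, cache$feats)
  dfeats <- dpreT %*% P$att_V + dpreS %*% P$att_U
  list(att_w = dw, att_V = dV, att_U = dU, dfeats = dfeats)
}

#' Gated-attention weights over patch features
#'
#' Computes `alpha_k = softmax_k( w' (tanh(V h_k) * sigm(U h_k)) )` -- a
#' softmax over tanh/sigmoid-gated scores, giving each patch a relevance
#' weight in `[0, 1]` that sums to one over the bag.
#'
#' @param features `(K, S)` matrix of patch features (or a list of length-S
#'   vectors).
#' @param params list with `w` (`L` x 1), `V` (`L` x `S`), `U` (`L` x `S`).
#' @return numeric vector of K attention weights summing to 1.
#' @export
gated_attention <- function(features, params) {
  if (is.list(features) && !is.matrix(features)) {
    features <- do.call(rbind, features)
  }
  if (!is.matrix(features) || nrow(features) < 1L) {
    stop("features must be a non-empty (K, S) matrix")
  }
  attention_forward(features, list(att_V = params$V, att_U = params$U,
                                   att_w = params$w))$alpha
}

#' Attention-weighted bag representation
#'
#' @param features `(K, S)` matrix.
#' @param alpha probability vector of length K.
#' @return length-S vector `z = sum_k alpha_k h_k`.
#' @export
attention_pool <- function(features, alpha) {
  if (is.list(features) && !is.matrix(features)) {
    features <- do.call(rbind, features)
  }
  if (nrow(features) != length(alpha)) {
    stop("features and alpha lengths do not match")
  }
  as.vector(crossprod(features, alpha))
}

#' Local-module class probabilities
#'
#' Sigmoid of a linear map of the pooled representation (no bias), one
#' output per class.
#'
#' @param z length-S vector from [attention_pool()].
#' @param head `(S, 2)` weight matrix, or a list with field `w_local`.
#' @return named numeric vector `c(benign=, malignant=)`, each in `(0, 1)`.
#' @export
local_predict <- function(z, head) {
  W <- if (is.list(head)) head$w_local else head
  if (length(z) != nrow(W)) stop("z length does not match head")
  p <- sigmoid(as.vector(z %*% W))
  names(p) <- c("benign", "malignant")
  p
}
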
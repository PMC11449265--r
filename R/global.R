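# Global module: per-slice feature extraction, the 1x1 semantic-segmentation
# saliency head, and slice-count-independent top-t% aggregation.

# ---- compact residual per-slice encoder --------------------------------------
#
# conv5x5/2 -> GN -> ReLU -> conv3x3/2 -> GN -> ReLU -> residual block
# (conv3x3 -> GN -> ReLU -> conv3x3 -> GN, skip, ReLU) -> k x k average pool,
# k = downsample/4. Group normalization (8 groups) keeps the statistics
# per-slice, so features are independent of batch composition and of the
# other slices in the stack.

init_global_backbone <- function(width, seed = NULL) {
  with_seed(seed, {
    list(
      g_conv1_W = init_conv_w(5L, 5L, 1L, width), g_conv1_b = rep(0, width),
      g_gn1_g = rep(1, width), g_gn1_b = rep(0, width),
      g_conv2_W = init_conv_w(3L, 3L, width, width), g_conv2_b = rep(0, width),
      g_gn2_g = rep(1, width), g_gn2_b = rep(0, width),
      g_conv3_W = init_conv_w(3L, 3L, width, width), g_conv3_b = rep(0, width),
      g_gn3_g = rep(1, width), g_gn3_b = rep(0, width),
      g_conv4_W = init_conv_w(3L, 3L, width, width), g_conv4_b = rep(0, width),
      g_gn4_g = rep(1, width), g_gn4_b = rep(0, width)
    )
  })
}

global_backbone_forward <- function(x, P, downsample) {
  k <- downsample %/% 4L
  c1 <- conv2d_forward(x, P$g_conv1_W, P$g_conv1_b, stride = 2L, pad = 2L)
  n1 <- group_norm_forward(c1$out, P$g_gn1_g, P$g_gn1_b)
  r1 <- relu_forward(n1$out)
  c2 <- conv2d_forward(r1$out, P$g_conv2_W, P$g_conv2_b, stride = 2L, pad = 1L)
  n2 <- group_norm_forward(c2$out, P$g_gn2_g, P$g_gn2_b)
  r2 <- relu_forward(n2$out)
  c3 <- conv2d_forward(r2$out, P$g_conv3_W, P$g_conv3_b, stride = 1L, pad = 1L)
  n3 <- group_norm_forward(c3$out, P$g_gn3_g, P$g_gn3_b)
  r3 <- relu_forward(n3$out)
  c4 <- conv2d_forward(r3$out, P$g_conv4_W, P$g_conv4_b, stride = 1L, pad = 1L)
  n4 <- group_norm_forward(c4$out, P$g_gn4_g, P$g_gn4_b)
  res <- tensor_new(n4$out$mat + r2$out$mat, n4$out$h, n4$out$w, n4$out$n)
  r4 <- relu_forward(res)
  pl <- avg_pool_forward(r4$out, k)
  list(out = pl$out,
       cache = list(c1 = c1, n1 = n1, r1 = r1, c2 = c2, n2 = n2, r2 = r2,
                    c3 = c3, n3 = n3, r3 = r3, c4 = c4, n4 = n4, r4 = r4,
                    pl = pl))
}

global_backbone_backward <- function(dout, cache) {
  g <- list()
  d <- avg_pool_backward(dout, cache$pl$cache)
  d <- relu_backward(d, cache$r4$cache)
  dskip <- d   # gradient through the residual connection
  bn4 <- group_norm_backward(d, cache$n4$cache)
  g$g_gn4_g <- bn4$dgamma; g$g_gn4_b <- bn4$dbeta
  bc4 <- conv2d_backward(bn4$dx, cache$c4$cache)
  g$g_conv4_W <- bc4$dW; g$g_conv4_b <- bc4$db
  d <- relu_backward(bc4$dx, cache$r3$cache)
  bn3 <- group_norm_backward(d, cache$n3$cache)
  g$g_gn3_g <- bn3$dgamma; g$g_gn3_b <- bn3$dbeta
  bc3 <- conv2d_backward(bn3$dx, cache$c3$cache)
  g$g_conv3_W <- bc3$dW; g$g_conv3_b <- bc3$db
  d <- tensor_new(bc3$dx$mat + dskip$mat, dskip$h, dskip$w, dskip$n)
  d <- relu_backward(d, cache$r2$cache)
  bn2 <- group_norm_backward(d, cache$n2$cache)
  g$g_gn2_g <- bn2$dgamma; g$g_gn2_b <- bn2$dbeta
  bc2 <- conv2d_backward(bn2$dx, cache$c2$cache)
  g$g_conv2_W <- bc2$dW; g$g_conv2_b <- bc2$db
  d <- relu_backward(bc2$dx, cache$r1$cache)
  bn1 <- group_norm_backward(d, cache$n1$cache)
  g$g_gn1_g <- bn1$dgamma; g$g_gn1_b <- bn1$dbeta
  bc1 <- conv2d_backward(bn1$dx, cache$c1$cache, need_dx = FALSE)
  g$g_conv1_W <- bc1$dW; g$g_conv1_b <- bc1$db
  g
}

# volume (H, W, D) -> tensor with one "sample" per slice
volume_to_tensor <- function(volume) {
  d <- dim(volume)
  tensor_new(matrix(as.vector(volume), ncol = 1L), d[1], d[2], d[3])
}

# ---- exported operations -----------------------------------------------------

#' Saliency nonlinearity ReLU(tanh(x))
#'
#' Maps pre-activations to `[0, 1]` while sending every non-positive input to
#' exactly zero, so background locations produce exactly-zero saliency (and
#' receive no gradient), unlike a sigmoid which outputs 0.5 at zero input.
#'
#' @param v numeric vector/array of finite values.
#' @return values in `[0, 1]`, same shape as `v`.
#' @export
#' @examples
#' relu_tanh(c(-3.2, 0, 1))
relu_tanh <- function(v) {
  stopifnot(all(is.finite(v)))
  out <- tanh(v)
  out[out < 0] <- 0
  out
}

#' Constant initialization of the segmentation layer
#'
#' Every weight of the 1x1 convolution mapping backbone channels to the two
#' class saliency planes starts at the same positive constant `omega` (bias
#' at zero). With equal positive weights, whichever channel of the backbone
#' responds to an important structure is carried into the saliency map with
#' the same positive sign, so top-t pooling starts by pooling from genuinely
#' salient locations rather than from channels that happened to receive a
#' negative random weight.
#'
#' @param c number of backbone channels.
#' @param omega positive constant, typically with `log10(omega)` in
#'   `(-3, -2)`.
#' @return list with `weights` (`c` x 2 matrix) and `bias` (length 2).
#' @export
init_segmentation_layer <- function(c, omega) {
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0) {
    stop("omega must be a positive scalar")
  }
  list(weights = matrix(omega, c, 2L), bias = c(0, 0))
}

#' Per-slice feature extraction
#'
#' Applies the 2D global encoder to every slice of the volume independently;
#' no information crosses slices, so duplicating or permuting slices
#' duplicates/permutes the feature planes identically.
#'
#' @param volume numeric `(H, W, D)` array with finite values.
#' @param model a `gmic3d` model (see [gmic3d_init()]).
#' @return feature stack: `(D, h, w, c)` array with attribute
#'   `downsample_factor`.
#' @export
extract_slice_features <- function(volume, model) {
  if (length(dim(volume)) == 2L) volume <- array(volume, c(dim(volume), 1L))
  if (length(dim(volume)) != 3L || dim(volume)[3] < 1L) {
    stop("volume must be a (H, W, D) array with D >= 1")
  }
  if (!all(is.finite(volume))) stop("volume contains non-finite values")
  fw <- global_backbone_forward(volume_to_tensor(volume), model$params,
                                model$config$backbone_downsample)
  tensor_to_feature_stack(fw$out, model$config$backbone_downsample)
}

tensor_to_feature_stack <- function(tn, downsample) {
  arr <- array(tn$mat, c(tn$h, tn$w, tn$n, ncol(tn$mat)))
  fs <- aperm(arr, c(3L, 1L, 2L, 4L))
  attr(fs, "downsample_factor") <- downsample
  fs
}

#' Class saliency maps from slice features
#'
#' Applies the 1x1 segmentation layer to each spatial location of each slice
#' and squashes with the saliency nonlinearity, producing one `[0, 1]` plane
#' per slice and class (class order: benign, malignant).
#'
#' @param features `(D, h, w, c)` feature stack from
#'   [extract_slice_features()].
#' @param layer segmentation layer, see [init_segmentation_layer()].
#' @param nonlinearity `"relu_tanh"` (default) or `"sigmoid"`.
#' @return `(h, w, D, 2)` saliency array with entries in `[0, 1]`.
#' @export
compute_saliency <- function(features, layer, nonlinearity = "relu_tanh") {
  dm <- dim(features)
  if (length(dm) != 4L) stop("features must be a (D, h, w, c) array")
  if (dm[4] != nrow(layer$weights)) {
    stop(sprintf("channel mismatch: features have %d channels, layer expects %d",
                 dm[4], nrow(layer$weights)))
  }
  fmat <- matrix(aperm(features, c(2L, 3L, 1L, 4L)), ncol = dm[4])
  logits <- sweep(fmat %*% layer$weights, 2L, layer$bias, "+")
  A <- if (nonlinearity == "sigmoid") sigmoid(logits) else relu_tanh(logits)
  array(A, c(dm[2], dm[3], dm[1], 2L))
}

# number of pooled entries: t% of a single slice's area, never less than 1,
# never more than the whole plane
top_t_count <- function(h, w, D, t) {
  if (t <= 0) stop("t must be positive")
  min(h * w * D, max(1L, round_half_up(t / 100 * h * w)))
}

#' Top-t percent saliency pooling, referenced to a single slice
#'
#' Averages the `n` largest values of a `(h, w, D)` saliency plane where
#' `n = round(t/100 * h * w)` depends on the slice area only -- not on the
#' number of slices -- so volumes with different slice counts contribute the
#' same number of pooled values. (With t = 200\% an `(h, w, 50)` plane pools
#' `2*h*w` entries, 4\% of the plane; an `(h, w, 80)` plane pools the same
#' count, 2.5\%.)
#'
#' @param class_plane numeric `(h, w, D)` array (a 2D matrix is treated as
#'   D = 1).
#' @param t pooling percentage of one slice's area, > 0.
#' @return scalar mean of the top-n entries; lies within the plane's range.
#' @export
aggregate_top_t <- function(class_plane, t) {
  dm <- dim(class_plane)
  if (is.null(dm)) stop("class_plane must be an array")
  if (length(dm) == 2L) dm <- c(dm, 1L)
  if (any(dm == 0L)) stop("empty saliency plane")
  n <- top_t_count(dm[1], dm[2], dm[3], t)
  v <- as.vector(class_plane)
  idx <- order(v, decreasing = TRUE)[seq_len(n)]
  structure(mean(v[idx]), pooled_idx = idx)
}

#' Global-module class probabilities
#'
#' @param saliency `(h, w, D, 2)` saliency array.
#' @param t pooling percentage (see [aggregate_top_t()]).
#' @return named numeric vector `c(benign=, malignant=)`, each in `[0, 1]`.
#' @export
global_predict <- function(saliency, t) {
  dm <- dim(saliency)
  stopifnot(length(dm) == 4L, dm[4] == 2L)
  p <- vapply(1:2, function(k) {
    as.numeric(aggregate_top_t(array(saliency[, , , k], dm[1:3]), t))
  }, numeric(1))
  names(p) <- c("benign", "malignant")
  p
}
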
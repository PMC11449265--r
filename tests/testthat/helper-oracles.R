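# Naive reference implementations used as oracles by the property tests.
# Everything here is a literal, unoptimized transcription of the definitions.

# sum of a matrix in explicit column-major double accumulation (the same
# addition order the optimized shifted-add criterion uses)
naive_rect_sum <- function(plane, ti, tj, rh, rw) {
  acc <- 0
  for (j in tj:(tj + rw - 1L)) {
    for (i in ti:(ti + rh - 1L)) {
      acc <- acc + plane[i, j]
    }
  }
  acc
}

# Literal transcription of the greedy retrieval: K times, scan every
# single-slice rectangle, keep the maximum (ties -> smallest (slice, top,
# left)), then zero the footprint across +/- zeta slices.
naive_retrieval <- function(saliency, K, zeta, patch_size, image_shape) {
  dm <- dim(saliency)
  h <- dm[1]; w <- dm[2]; D <- dm[3]
  H <- image_shape[1]; W <- image_shape[2]
  rh <- max(1L, min(h, as.integer(floor(patch_size * h / H + 0.5))))
  rw <- max(1L, min(w, as.integer(floor(patch_size * w / W + 0.5))))
  mm <- function(p) {
    if (max(p) == min(p)) return(p * 0)
    (p - min(p)) / (max(p) - min(p))
  }
  astar <- mm(array(saliency[, , , 1], dm[1:3])) +
    mm(array(saliency[, , , 2], dm[1:3]))
  if (length(dim(astar)) != 3L) astar <- array(astar, dm[1:3])
  out <- data.frame(rank = seq_len(K), slice = NA_integer_,
                    top = NA_integer_, left = NA_integer_)
  for (k in seq_len(K)) {
    best_v <- -Inf
    best <- c(NA, NA, NA)
    for (d in seq_len(D)) {
      for (tj in seq_len(w - rw + 1L)) {
        for (ti in seq_len(h - rh + 1L)) {
          v <- naive_rect_sum(matrix(astar[, , d], h, w), ti, tj, rh, rw)
          if (v > best_v ||
              (v == best_v && (d < best[1] ||
                               (d == best[1] && (ti < best[2] ||
                                (ti == best[2] && tj < best[3])))))) {
            best_v <- v
            best <- c(d, ti, tj)
          }
        }
      }
    }
    d <- as.integer(best[1]); ti <- as.integer(best[2]); tj <- as.integer(best[3])
    out$slice[k] <- d - 1L
    out$top[k] <- as.integer(min(max(floor((ti - 1L) * H / h + 0.5), 0),
                                 H - patch_size))
    out$left[k] <- as.integer(min(max(floor((tj - 1L) * W / w + 0.5), 0),
                                  W - patch_size))
    zlo <- max(1L, d - zeta); zhi <- min(D, d + zeta)
    astar[ti:(ti + rh - 1L), tj:(tj + rw - 1L), zlo:zhi] <- 0
  }
  out
}

# all-pairs Mann-Whitney AUC, ties counted one half
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# pixel AP by explicit threshold enumeration over the distinct scores
naive_pxap <- function(scores, truth) {
  s <- as.numeric(scores)
  t <- as.numeric(truth > 0)
  th <- sort(unique(s), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (x in th) {
    sel <- s >= x
    prec <- sum(t[sel]) / sum(sel)
    rec <- sum(t[sel]) / sum(t)
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# central finite-difference gradient of f at x (a numeric array), flattened
fd_grad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# relative difference robust to zero gradients
rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# internal helpers reused across tests
with_seed <- gmic3d:::with_seed
derive_seed <- gmic3d:::derive_seed
round_half_up <- gmic3d:::round_half_up

# small random volume helper
rand_volume <- function(H, W, D, seed = 1) {
  with_seed(seed, array(stats::runif(H * W * D), c(H, W, D)))
}
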
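---
title: "Methods: two-stage weakly-supervised classification of 3D stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage weakly-supervised classification of 3D stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(gmic3d)
```

## The problem

A reconstructed tomosynthesis stack is a large 3D grayscale array — around
2116 × 1339 pixels per slice and tens of slices — in which the objects that
determine the label (lesions) occupy a fraction of a percent of the voxels.
Annotated lesion outlines are rarely available at scale, so the model must
train from **image-level labels only**: one bit per class
(benign/malignant findings present or not) per volume. `gmic3d` implements
a two-stage architecture for this regime, together with a seeded phantom
generator that reproduces its geometry at desk scale (64 × 64 slices, 4–8
slices per stack) so every component can be exercised end-to-end on one
CPU.

Two properties of reconstructed stacks drive the design:

1. A structure is visible on *many* slices, in focus on one of them, with
   an identical in-plane footprint — a stack is closer to "one image seen
   at many focal depths" than to an isotropic 3D volume.
2. The discriminative evidence is tiny relative to the input, so global
   pooling of a whole-volume feature map washes it out.

## Stage one: the global module

Every slice is passed independently through a small convolutional encoder
(strided convolutions, group normalization so statistics never mix slices
or batch entries, one residual block). A 1 × 1 convolution with **all
weights initialized to a constant** ω maps the per-slice feature grid to
two class planes, and an elementwise `ReLU(tanh(x))` squashes them into
[0, 1]. Stacking the slices yields the 4D **saliency map**
`A ∈ [0,1]^(h, w, D, 2)` — the model's localization output.

The constant initialization makes the saliency map a *sum of feature
channels* at the start of training, so patch retrieval (below) is already
informative at epoch one; random init would start retrieval from noise.

```{r saliency}
model <- gmic3d_init(gmic3d_config("desk"), seed = 1)
ph <- generate_phantom(phantom_spec(), seed = 42)
out <- gmic3d_forward(model, ph$volume)
dim(out$saliency)
```

### Slice-count-independent top-t% pooling

The global class probability averages the largest saliency values. The
pooled count is referenced to the area of **one slice**:

```
n = min(h · w · D, max(1, round(t/100 · h · w)))
```

so a 50-slice stack and an 80-slice stack contribute the *same number* of
pooled entries. With `t = 200%` the pooled entries are 4% of an
`(h, w, 50)` saliency volume and 2.5% of an `(h, w, 80)` one:

```{r pooling}
n <- function(D) length(attr(aggregate_top_t(array(runif(40 * 30 * D),
                                                   c(40, 30, D)), 200),
                             "pooled_idx"))
c(frac_50 = n(50) / (40 * 30 * 50), frac_80 = n(80) / (40 * 30 * 80))
```

Appending empty slices therefore leaves the global prediction unchanged —
the property that lets one model handle stacks of any depth:

```{r zero-slices}
x <- array(runif(6 * 7 * 3), c(6, 7, 3))
x2 <- array(0, c(6, 7, 9)); x2[, , 1:3] <- x
c(aggregate_top_t(x, 50), aggregate_top_t(x2, 50))
```

## Patch retrieval (greedy, with slice suppression)

The local module needs a few small 2D crops that contain the evidence. Both
class saliency planes are min–max normalized and summed into a criterion
map `A*`; then, greedily, K times: pick the position of the
patch-sized rectangle (on a *single* slice) with the largest criterion sum
(ties broken toward the lexicographically smallest (slice, top, left)),
map it to image coordinates, and **zero the rectangle's footprint across
the ±ζ neighboring slices** so near-duplicate in-focus/out-of-focus copies
of the same structure are not retrieved twice. During training the
selected slice is resampled uniformly within ±ζ, a cheap augmentation
along depth. Patch coverage is tiny by construction — the point of the
architecture:

```{r coverage}
c(image_pct = as.numeric(patch_coverage(c(2116, 1339), 8, 256)),
  volume_pct = as.numeric(patch_coverage(c(2116, 1339, 70), 8, 256)))
```

```{r retrieval}
out$locations
```

## Stage two: the local module

Each retrieved patch is encoded to a feature vector `h_k`; a **gated
attention** layer scores the bag,

```
α_k = softmax_k( wᵀ ( tanh(V h_k) ⊙ sigmoid(U h_k) ) )
```

and the attention-weighted sum of features feeds a sigmoid head, giving
`p_local`. Attention weights form a probability vector, a singleton bag
gets weight 1, and identical patches get exactly uniform weights. The
final prediction averages the stages: `p_final = (p_global + p_local)/2`.

## Loss

Both stages are supervised *separately* for each class `c`:

```
L = Σ_c [ BCE(y_c, p_local,c) + BCE(y_c, p_global,c) ] + β Σ |A|
```

The L1 term pushes saliency toward zero except where evidence lives —
this, not any pixel label, is what makes the saliency map a segmentation.
Using separate BCEs (rather than the BCE of the averaged prediction)
keeps gradient pressure on both modules:

```{r loss}
mk <- function(pl, pg) list(p_local = pl, p_global = pg,
                            saliency = array(0, c(2, 2, 2, 2)))
c(perfect = total_loss(c(1, 0), mk(c(1, 0), c(1, 0)), beta = 1),
  coin = total_loss(c(0, 0), mk(c(.5, .5), c(.5, .5)), 1), four_ln2 = 4 * log(2))
```

## Desk-scale study

The phantom generator stamps round (benign) or spiculated (malignant)
lesions with an identical footprint on every slice and contrast decaying
exponentially away from a focus slice — tiny (< 1% of voxels), as in the
motivating clinical regime. A complete end-to-end run — generate a few
hundred phantoms, fit with `gmic3d()`, evaluate AUC and weakly-supervised
segmentation metrics — is shown in the package README and in
`scripts/acceptance.R`; it takes a few minutes on one CPU. The short
version:

```{r study, eval = FALSE}
spec <- phantom_spec()
make <- function(n, off) lapply(seq_len(n), function(i) {
  ph <- generate_phantom(spec, seed = i + off)
  list(volume = ph$volume, labels = ph$labels, masks = ph$masks)
})
fit <- gmic3d(list(train = make(200, 0), val = make(30, 1000)),
              config = gmic3d_config("desk"), seed = 1)
evaluate_classification(fit, make(30, 2000))
```

## Evaluation protocol

* **AUC** (exact Mann–Whitney form, midranks for ties), optionally
  group-averaged when several views share a subject.
* **PxAP** — pixel average precision of the saliency ranking against the
  truth mask, and **Dice** at the best of 19 thresholds, both computed on
  depth **max-projections** so stacks of different depth are comparable.
* **Inside/outside ratio** — mean saliency inside the (grid-downsampled)
  truth mask over mean saliency outside; a trained model concentrates
  saliency by orders of magnitude.
* **MAC accounting** — `gmic3d_layer_spec()` + `count_macs()` show the
  global cost scaling linearly in D while the local cost is constant — the
  architecture's compute argument in one table.

```{r macs}
cfg <- gmic3d_config("paper")
sapply(c(10, 40, 70), function(D)
  count_macs(gmic3d_layer_spec(cfg, c(2116, 1339, D))) / 1e9)
```
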
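Package: gmic3d
Title: Weakly-Supervised Classification and Localization of Small
    Lesions in 3D Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage weakly-supervised classifier for large 3D
    grayscale stacks (e.g. digital breast tomosynthesis) containing
    small objects. A per-slice global network produces class saliency
    volumes that are pooled with a slice-count-independent top-t%
    aggregation; a greedy retrieval algorithm crops a few informative
    2D patches while suppressing near-duplicate slices; a gated-attention
    local network refines the prediction. Trained from image-level
    labels only, with saliency maps as the localization output.
    Includes a seeded phantom generator for tomosynthesis-like stacks,
    classification and weakly-supervised segmentation metrics, and
    analytic compute accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
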
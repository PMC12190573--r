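Package: liunet
Title: Lightweight 3D Inception U-Net for Multimodal Brain-Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained implementation of LIU-Net, a five-level 3D
    encoder-decoder segmentation network with Inception-style multi-scale
    convolution blocks, for BraTS-layout multimodal brain MRI (FLAIR, T1,
    T1ce, T2). Provides NIfTI cohort I/O with label remapping and seeded
    train/validation/test splitting, intensity normalization and volume
    resampling, the composite Dice + Focal training objective, per-region
    (enhancing tumor, tumor core, whole tumor) Dice evaluation, a synthetic
    ellipsoid phantom generator so the full pipeline is testable without
    the BraTS download, and a CPU training engine (Adam, manual
    backpropagation) returning a classed model object with the usual
    print/summary/predict/plot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
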
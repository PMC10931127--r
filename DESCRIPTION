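Package: pgvce
Title: Virtual Contrast Enhancement of MRI with a Pixelwise Gradient GAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesizes virtual-contrast-enhanced T1-weighted (T1C) MRI
    slices from co-registered pre-contrast T1-weighted and T2-weighted
    slices. The generator is a dual-encoder U-Net with gated modality
    fusion trained against a pixelwise normalized-gradient shape loss
    combined with a least-squares GAN patch-discriminator contrast loss.
    Includes per-patient intensity normalization (z-score, sigmoid, tanh)
    with exact inverses, similarity metrics (MAE, MSE, global SSIM),
    four scale-invariant texture/sharpness metrics (total mean-square and
    total absolute variation, Tenengrad, and variance, each per mean
    intensity), modality-ablation ratios, a synthetic multi-tissue head
    phantom generator for end-to-end testing without patient data, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
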
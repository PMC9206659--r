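Package: pshg
Title: Widefield Polarimetric Second-Harmonic Generation Tissue Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for widefield polarimetric second-harmonic
    generation (P-SHG) microscopy of collagenous tissue. Reconstructs reduced
    SHG Stokes-vector maps from 16 polarization-state intensity images,
    derives per-pixel polarimetric parameter maps (circular-input SHG
    intensity, nonlinear susceptibility R-ratio, degree of circular
    polarization, SHG circular and linear dichroism), computes masked
    grey-level co-occurrence texture features over sub-images, screens
    features with Kruskal-Wallis and Dunn-Bonferroni tests, and classifies
    tissue with a binary logistic-regression model evaluated by repeated
    stratified cross-validation. Includes a physics-based synthetic
    collagen-fiber image simulator that provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    glmnet
Config/testthat/edition: 3
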
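Package: fgscreen
Title: Three-Stage Ensemble Screening of Fetal Genetic Disorders from
    Midsagittal Ultrasound Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates a three-stage ensemble pipeline for screening
    fetal genetic disorders from midsagittal fetal-profile ultrasound images:
    a single-stage anchor-based detector with a BiFPN fusion neck and efficient
    channel attention localizes seven anatomical regions of interest; per-region
    residual convolutional networks with convolutional block attention estimate
    a disorder risk for each region; and gradient-boosted trees stack the
    per-region risks into a final disorder probability, with Grad-CAM heatmaps
    for interpretability. Includes homomorphic-filter illumination correction,
    letterbox resizing, Trivial Augment, detection and classification metrics
    with brute-force oracles, and a synthetic speckle-textured phantom generator
    with planted, label-dependent region morphology so the whole pipeline is
    trainable and testable at desk scale without patient data. All neural
    operators run on a compact built-in CNN engine with exact backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    xgboost,
    withr,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
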
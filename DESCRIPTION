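Package: kidseg
Title: Coarse-to-Refinement Kidney Ultrasound Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage toolkit for kidney boundary extraction in 2D
    ultrasound images. Stage one is a deep fusion learning network: a U-Net
    whose skip connections are augmented with squeeze-and-excitation and
    attention-gate modules in four serial/parallel fusion variants, trained
    with Dice loss and Adam. Stage two refines the coarse mask with an
    automatic searching polygon tracking method (adaptive mean-shift vertex
    discovery plus a modified penalized-distance vertex optimization) and
    fits an adaptive learning-rate backpropagation network that yields an
    explainable closed-form parameterization of the contour. Includes a
    synthetic ultrasound-phantom generator with exact ground truth, Dice and
    Jaccard evaluation, an ablation harness, and a Gaussian-noise robustness
    protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
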
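Package: asnet
Title: Self-Organized Deep Feature Engineering for Two-Class Medical Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a self-organized deep feature engineering pipeline for
    two-class medical image classification. Six layer-wise deep feature matrices
    from three pretrained convolutional backbones (or a dependency-free toy
    extractor) are each reduced by three filter selectors (neighborhood component
    analysis, ReliefF, chi-square) to the 272 most informative features, classified
    by a standardized 1-nearest-neighbor classifier under stratified 10-fold
    cross-validation, and the resulting 18 prediction vectors are fused by
    iterative majority voting into 16 voted outcomes; the best of all 34 candidate
    outcomes is selected by accuracy. Includes seeded synthetic fixture generators
    for feature matrices and two-class phantom images, confusion-matrix metric
    panels, and report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    EBImage,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
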
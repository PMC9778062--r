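Package: aptacolor
Title: Image-Based Quantification of Amoxicillin from AuNP-Aptamer
    Colorimetric Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for quantifying amoxicillin concentration from RGB images
    of gold-nanoparticle (AuNP) aptamer colorimetric assays. Provides a seeded
    synthetic well-image generator driven by a Hill dose-response aggregation
    model, image preprocessing (median filtering, circle Hough segmentation,
    Gaussian smoothing, cropping to the inscribed square), nine-value
    color-moment feature extraction, a from-scratch 9-18-1 backpropagation
    neural-network regressor with momentum, and assay calibration statistics
    (R-squared, mean squared error, IUPAC limit of detection, spike recovery
    and relative standard deviation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    graphics,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
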
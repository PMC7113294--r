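Package: octbiofilm
Title: Structural Biofilm Parameters and Positioning Accuracy from OCT C-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structural analysis of biofilms imaged by optical
    coherence tomography (OCT). Reads C-scan volumes from multi-page TIFF
    stacks, applies the standard mean-filter/binarization workflow, and
    computes substratum coverage, mean biofilm thickness, intrinsic and
    global porosity, gray-level co-occurrence textural entropy, and
    bulk-biofilm interface height maps. Also evaluates the positioning
    accuracy of an automated scanning stage from images of a printed
    calibration target (center-of-mass deviations, 1.5*IQR outlier flags),
    provides Grubbs outlier testing and replicate summaries for flow-cell
    experiments, and ships a synthetic phantom generator with known ground
    truth so the whole pipeline is testable without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    png,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
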
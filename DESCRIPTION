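Package: dentseg
Title: Automatic Tooth Segmentation and Crown Morphometrics for Digital Dental Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for automatic segmentation of digital dental models
    (triangle-mesh intraoral scans) into individual teeth and gingiva. A
    two-stage point-cloud edge-convolution network performs a coarse
    tooth/gingiva split with gingiva point-budget balancing followed by a
    seventeen-class per-tooth labelling; curvature-based margin refinement
    sharpens the cervical margin via feature-vertex skeleton pruning into
    closed loops. Includes a procedural generator of labelled synthetic
    dental arches with known ground truth, crown measurement (mesiodistal
    width, clinical crown height) against a fitted virtual occlusal plane
    with a +/-25 percent success criterion, and the accompanying agreement
    statistics (success rates, Cohen's kappa, two-way random ICC, Friedman
    test, Cochran's Q).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
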
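Package: spherotil
Title: Quantification of CTL Killing, Infiltration and Morphodynamics in
    Tumor Spheroid Assays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cytotoxic T lymphocyte (CTL) / tumor
    interaction assays: 3D tumor-spheroid segmentation from half-acquired
    confocal z-stacks (mirror completion, thresholding, connected components,
    alpha-hull gap filling, distance-based watershed) with
    spheroid-infiltrating lymphocyte densities and dead-volume kinetics;
    microscope-based cytotoxicity killing rates from red-object area time
    series; cell-couple morphodynamics classifiers (tight coupling, uropod,
    off-interface lamellae, translocation) with Kaplan-Meier/log-rank
    time-to-event analysis and Fura-2 calcium ratios; caliper tumor-growth
    statistics (modified elliptical volume, R-value growth rate,
    responder/relapse/remission classification, exact 2x2 tests including
    Boschloo's unconditional test, proportion z-test, power-based sample
    size); and Boolean-gated marker-combination PCA with cos2/contribution
    scores and 95% group ellipses. Includes synthetic-data generators with
    known ground truth for every input modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
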
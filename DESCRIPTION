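Package: shapegrade
Title: Shape-Based Radiomics and Surface Regularity for Meningioma Grading
Version: 0.1.0
Authors@R:
    person("Shapegrade", "Developers", email = "shapegrade@example.org",
           role = c("aut", "cre"))
Description: Computes surface regularity and the size-invariant 3D shape
    radiomics features sphericity, elongation and flatness from binary tumor
    segmentation masks (NIfTI), and runs the associated grading statistics:
    linear regression of each feature on mitotic rate, one-way ANOVA and
    pairwise t-tests across WHO meningioma grades, ROC/AUROC with bootstrap
    or DeLong confidence intervals, and Youden cutoff selection. Includes a
    synthetic-phantom generator (spherical-harmonic-perturbed balls and
    calibrated cohorts) so the full pipeline is testable without patient
    data, plus a command-line interface for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
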
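Package: strainTDA
Title: Topological Motifs from Segmental Cardiac Strain Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts segmental echocardiographic strain and strain-rate
    time series into topological feature vectors and uses them to separate
    clinically similar heart-failure phenotypes. Regional mean strain
    curves are delay-embedded into point clouds, dimension-0 persistent
    homology of the Vietoris-Rips filtration is summarised as linear
    persistence images, and the 18 images per patient are stacked into an
    18 x 50 "motif" whose 900 pixel intensities feed shadow-feature
    (Boruta-style) selection, cross-validated classifiers with ROC/AUC and
    paired DeLong comparisons against a global-longitudinal-strain
    baseline, and Shapley attributions. Includes a synthetic cohort
    generator emulating class-dependent strain amplitude, regional
    heterogeneity, timing and noise so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
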
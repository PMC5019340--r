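Package: desilasso
Title: Pixel-Level Tissue Classification for DESI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying pixels of desorption electrospray ionization
    mass spectrometry imaging (DESI-MSI) scans into tissue classes (pancreatic
    cancer, normal glands, normal stroma) with an L1-penalized multinomial
    logistic model. Provides spectral binning of the 13,320-channel negative
    ion mode mass axis into 2,220 features, a coordinate-descent lasso path
    solver with leave-one-patient-out cross-validation, a customized-training
    variant that fits cluster-local models for mixed-histology test samples,
    agreement scoring against pathology annotations (confusion matrices,
    per-class agreement with binomial standard errors, majority-rule verdicts,
    percent-composition comparison, surgical-margin flagging), a synthetic
    multi-patient cohort generator for end-to-end testing, ion-image and
    prediction-map rendering, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
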
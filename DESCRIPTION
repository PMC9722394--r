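Package: nirsconn
Title: Resting-State Functional Connectivity Screening for Multichannel fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of resting-state functional near-infrared
    spectroscopy (fNIRS) recordings for two-group connectivity screening:
    signal-to-noise quality control, moving-window motion-artifact detection
    with smoothing-spline correction, zero-phase band-pass filtering,
    modified Beer-Lambert inversion of dual-wavelength optical density to
    oxy-/deoxy-hemoglobin, Pearson/Fisher-z connectivity at channel and
    region-of-interest level, mass-univariate edge statistics with
    false-discovery-rate control and ROC screening, and repeated stratified
    cross-validated linear discriminant classification. Includes a
    calibrated two-group synthetic cohort generator so the whole pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
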
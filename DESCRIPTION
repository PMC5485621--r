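Package: synctdose
Title: Dosimetric Evaluation of Synthetic CT for MR-Only Lung Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Builds digital thorax phantoms with simulated two-point Dixon MR
    signal pairs, generates synthetic CT volumes by rule-based tissue
    classification and atlas-based bone insertion, computes heterogeneity-
    corrected photon dose with a simplified ray-marching engine, and
    quantifies agreement between synthetic-CT and reference-CT dose
    distributions with dose-volume-histogram metrics, global 3D gamma
    analysis, and paired statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
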
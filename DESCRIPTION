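Package: sctqa
Title: Quality Assurance Metrics for Synthetic CT in MRI-Only Adaptive
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for comparing a synthetic CT (sCT) against
    a deformably registered reference CT (dCT) in MRI-guided adaptive
    radiotherapy. Implements volume-of-interest construction with body
    masking and air-pocket compensation, Hounsfield-unit agreement metrics
    (mean error, mean absolute error globally and in 20-HU bins), Dice
    similarity of threshold tissue masks, electron-density calibration,
    structure-wise dose-volume-histogram points in physical dose and
    biologically effective dose with fraction-wise accumulation, local 3D
    gamma analysis, displacement-field resampling of doses and structures,
    and a self-contained digital phantom generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
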
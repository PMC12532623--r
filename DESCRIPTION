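Package: sinusid
Title: Frontal-Sinus Silhouette Matching for Radiographic Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative identification from two-dimensional
    frontal-sinus silhouettes extracted from axial CT slices. Provides a
    synthetic silhouette generator with antemortem/postmortem pairing,
    Hounsfield-unit thresholding and canvas normalization, two from-scratch
    binary keypoint pipelines (an ORB-style FAST/Harris/steered-BRIEF
    extractor and an AKAZE-style nonlinear-scale-space/M-LDB extractor),
    brute-force Hamming matching with a mean-distance similarity score, and
    the evaluation statistics used in identity verification: Welch's t-test,
    ROC analysis with Youden cutoffs, subgroup splits, and technical error
    of measurement (TEM, rTEM) with the coefficient of reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    withr,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
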
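Package: petsac
Title: Semiautomatic PET Lesion Segmentation with Self-Adaptive Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomatic segmentation of FDG-avid lesions on PET volumes in
    standardized uptake value (SUV) units, inside observer-drawn regions of
    interest: absolute and relative SUV thresholding, percentile-initialized
    one-dimensional k-means, Gaussian-mixture maximum-a-posteriori
    classification, and a contrast-driven self-adaptive configuration (SAC)
    rule that fits three intensity classes and merges two of them.  Includes
    lesion quantification (SUVmax, SUVmean, SUVpeak, metabolic tumor volume,
    total lesion glycolysis, first-order, geometric and dissemination
    features), agreement evaluation (Dice coefficient, absolute-agreement
    intraclass correlation), and a digital phantom generator with known
    ground truth and simulated observer variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    withr
Config/testthat/edition: 3
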
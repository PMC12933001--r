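Package: ecglvh
Title: Left Ventricular Hypertrophy Prediction from Median-Beat
    Electrocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for predicting cardiac magnetic resonance
    derived left ventricular hypertrophy (LVH) from resting multi-lead
    electrocardiograms and clinical covariates. Provides signal-averaged
    median-beat extraction (Butterworth bandpass, principal-component R-peak
    detection, cross-correlation beat alignment with rejection of
    uncorrelated beats), clinical variable derivation (Mosteller body
    surface area, medication-adjusted blood pressure and cholesterol,
    condition definitions), a fully convolutional network trained with a
    log-cosh loss to regress indexed left ventricular mass, logistic
    recalibration into sex-specific LVH decision thresholds, classical
    Sokolow-Lyon and Cornell voltage criteria, diagnostic statistics
    (AUROC with analytic confidence intervals, DeLong tests, Youden
    operating points, Bland-Altman agreement, bootstrap error intervals),
    integrated-gradients attribution, and a seeded synthetic-cohort
    generator so that the full pipeline is testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
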
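Package: emgkin
Title: Continuous Joint-Angle Estimation from Surface EMG During Loaded Squats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for continuous estimation of knee and ankle
    sagittal-plane joint angles from five-channel surface electromyography
    (sEMG) recorded during squats under different loading conditions.
    Provides zero-phase Butterworth filtering, squat-cycle segmentation at
    kinematic local minima with cubic-spline resampling, min-max
    normalization, symlet (sym8) level-8 wavelet approximation features,
    cross-correlation estimation of the electromechanical delay with
    finite-support lag alignment, from-scratch LSTM and MLP regressors
    (RcppArmadillo training backend), leave-one-subject-out evaluation with
    RMSE and Pearson-r reporting, and a synthetic-data generator with known
    ground-truth lags and load-dependent range of motion so the whole
    pipeline is testable without access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
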
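Package: ppgvitals
Title: Respiration Rate and Oxygen Saturation Estimation from Photoplethysmogram Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for estimating respiration rate (breaths per
    minute) and peripheral oxygen saturation (SpO2, percent) from single-channel
    photoplethysmogram (PPG) waveforms. Provides zero-phase Butterworth
    filtering, variational mode decomposition (VMD) based motion-artifact
    removal, pulse-wave fiducial delineation (onset, systolic peak, dicrotic
    notch, diastolic peak, second-derivative a-e waves), a fixed catalog of 107
    morphological, spectral and statistical features, feature ranking by
    Gaussian-process automatic relevance determination, RReliefF, LASSO entry
    order and the Laplacian score, a five-family regression model zoo evaluated
    under 5-fold 60/20/20 cross-validation, Bland-Altman agreement analysis,
    and a physiologically structured synthetic PPG generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    glmnet,
    e1071,
    rpart,
    randomForest,
    xgboost,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
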
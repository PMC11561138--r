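Package: kneeload
Title: Knee Joint Contact Force Peak Prediction from Portable Gait Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for predicting the nine stance-phase peaks of the
    tibiofemoral (knee joint) contact force from simple subject-level
    predictors: mass, height, age, sex, walking speed, and a knee flexion
    angle (KFA) summary. Walking speed and the KFA predictor are estimated
    either from inertial measurement unit (IMU) streams (orientation plus
    acceleration at 100 Hz) or from sagittal-plane 2D pose keypoints.
    Predictions are made with single-hidden-node feedforward networks trained
    by Levenberg-Marquardt backpropagation with Bayesian regularization, and
    with a first-order multiple linear regression baseline. A deterministic
    synthetic gait simulator generates cohorts, IMU streams, keypoint streams
    and loading curves with known ground truth so the full pipeline can be
    exercised end-to-end without laboratory data, and an evaluation module
    builds balanced test sets and computes RMSE, NRMSE, Pearson correlation
    and mean-absolute-error change metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
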
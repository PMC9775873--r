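Package: crmwave
Title: Compensatory Reserve Estimation from Arterial Blood Pressure Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring simulated hemorrhage and resuscitation from
    continuous arterial blood pressure (ABP) waveforms. Includes a synthetic
    lower-body negative pressure (LBNP) session generator with per-beat ground
    truth, beat segmentation and fiducial-point detection (including dicrotic
    notch selection), nine pulse-morphology features, robust outlier rejection
    and windowed averaging, gradient-boosted and ordinary-least-squares
    regression of the compensatory reserve metric (CRM) with subject-wise
    cross-validation, and an evaluation battery (RMSE, R-squared, ROC AUC at
    clinical CRM thresholds, Bland-Altman agreement, Gini feature importance,
    per-ramp-speed summaries).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    signal,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
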
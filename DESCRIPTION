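Package: spiralpen
Title: Smart Ink Pen Spiral-Drawing Analysis for Parkinson's Disease Motor Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spiral drawings recorded with a sensorized
    ink pen (tri-axial accelerometer, tri-axial gyroscope, tip-force load cell,
    50 Hz). Computes motor-deficit indicators across seven domains (kinematics,
    force, smoothness, tilt, frequency, amplitude, tremor regularity) including
    spectral arc length, log dimensionless jerk, empirical-mode-decomposition
    tremor extraction, Welch band powers, approximate entropy, recurrence
    quantification and the tremor stability index. Provides cohort statistics
    (normality-gated group tests, Spearman correlation with clinical scales,
    Fisher-z sample-size calculation), leave-one-out classification of
    Parkinson's disease versus control with per-indicator Shapley attribution,
    and a synthetic recording generator so the full pipeline runs without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    nortest,
    randomForest,
    xgboost,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
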
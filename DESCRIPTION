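Package: gaitsev
Title: Gait-Based Dementia Severity Analysis from Wearable IMU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for inertial-measurement-unit
    (IMU) gait recordings in a four-group cognitive cohort (healthy control,
    mild cognitive impairment, mild dementia, moderate dementia). Synthesizes
    multi-segment gyroscope/accelerometer walking trials calibrated to
    published group-level gait summaries; extracts eleven spatiotemporal and
    sagittal joint-angle parameters via zero-phase Butterworth filtering,
    gyroscope-peak gait-event detection, complementary-filter orientation
    estimation and an inverted-pendulum step-length model; ranks features
    with multiclass ReliefF; classifies severity with a cross-validated
    support vector machine; and reproduces the accompanying nonparametric
    statistical battery (Kruskal-Wallis with Bonferroni post hoc, Fisher's
    exact test, logistic regression with max-rescaled R-squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
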
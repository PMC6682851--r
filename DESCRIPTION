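Package: mammotriage
Title: AI-Based Pre-Selection of Normal Screening Mammograms with
    Split-Plot MRMC Non-Inferiority Analysis
Version: 0.1.0
Authors@R:
    person("Screening", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and evaluates triage of screening mammography
    exams by a calibrated 10-category artificial-intelligence suspicion
    score. Provides a seeded multi-reader multi-case (MRMC) cohort
    generator with a split-plot study design, decile calibration of
    continuous scores on normal exams, threshold-sweep partitioning into
    low- and high-likelihood groups with workload/exclusion trade-off
    statistics, radiologist-score reassignment for excluded exams, and
    reader-averaged nonparametric ROC analysis: trapezoidal AUC,
    area-preserving curve averaging perpendicular to the chance line, an
    unbiased U-statistic variance estimator for reader-averaged AUC on
    arbitrary (not fully crossed) designs, and Bonferroni-corrected
    non-inferiority tests of AUC differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
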
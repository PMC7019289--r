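Package: adaptaste
Title: Bayesian Adaptive Yes-No Procedures for Taste Threshold Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two Bayesian adaptive yes-no procedures for measuring
    taste recognition thresholds: a QUEST variant that tracks a single
    threshold parameter on a Weibull-type psychometric function, and a quick
    Yes-No (qYN) procedure that estimates threshold, slope, and decision
    criterion simultaneously on a three-dimensional parameter grid using a
    signal-detection d-prime sensitivity function. Ships the standard tastant
    concentration ladders (citric acid, sodium chloride, quinine
    hydrochloride, sucrose) on decadic logarithmic grids, a seeded
    simulated-observer engine for parameter-recovery and test-retest
    experiments, and test-retest agreement statistics (Spearman rank
    correlation, Bland-Altman mean difference, coefficient of repeatability,
    limits of agreement with exact-paired confidence intervals, and a
    log10 pathway with back-transformation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
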
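Package: ditchamber
Title: Diet-Induced Thermogenesis from Whole-Room Indirect Calorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates diet-induced thermogenesis (DIT) from whole-room
    indirect-calorimetry chamber sessions by two approaches: a
    fasting-calibration method that predicts non-DIT energy expenditure from
    an individually fitted regression of energy expenditure on physical
    activity intensity measured in the fasted state, and the classical
    regression-intercept (Schutz) method based on postprandial 30-minute
    bins. Includes the accelerometer and infrared-sensor signal chain
    (high-pass filtering, vector-magnitude activity index, minute
    aggregation), Weir-equation energy expenditure, sleeping and basal
    metabolic rate derivation, a validity and test-retest reproducibility
    statistics battery (one-sample and paired t-tests, variance-homogeneity
    F-tests, Bland-Altman limits, within-subject coefficient of variation),
    and a seeded chamber-session simulator with known ground-truth
    decomposition of energy expenditure into basal, activity-related and
    thermogenic components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
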
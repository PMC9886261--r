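Package: actifrail
Title: Physical-Function Features and Frailty Classification from Trunk-Worn
    Accelerometer and Barometer Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns 24-hour trunk-worn tri-axial accelerometer (50 Hz) and
    barometer (5 Hz) recordings into nine daily physical-function features:
    activity rate, sleep calmness, step count, movement periodicity rate and
    period, weightlessness time, lift and stair counts from barometric
    altitude, and MET-based energy expenditure. Provides cohort-level
    scaling (z-score and sigmoid), Wilcoxon rank-sum feature retention,
    two-component PCA views, and leave-subject-out evaluation of five
    classifier families under daily and 5-day (feature-averaging and
    majority-voting) decision designs, together with a synthetic-data
    generator that emits signal-level recordings with ground-truth episode
    logs and calibrated frail/robust feature cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nnet,
    e1071,
    class,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
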
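Package: pamthresh
Title: Confidence-Score Calibration and Vocal-Activity Profiles for
    Automated Acoustic Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-classifier analysis for passive acoustic monitoring surveys
    that use automated bird-song recognizers emitting per-segment confidence
    scores (BirdNET-style tabular output). Provides stratified verification
    sampling of predictions by confidence bin, precision estimation per score
    class, logistic calibration of confidence scores on the logit scale,
    inversion of the fitted model to the confidence threshold that attains a
    target probability of correct identification (with explicit failure
    statuses), and diel and annual vocal-activity profiles from
    threshold-filtered detections. A synthetic-data generator emulates a
    year-round, multi-station duty-cycled recording design so the full
    pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
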
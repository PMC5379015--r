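Package: kinectcpt
Title: Scoring Engine for Motion-Tracked Continuous Performance Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a Kinect-based continuous performance
    test (CPT) in which the examinee raises the dominant hand to non-X
    stimuli and withholds the movement for the forbidden X-stimulus.
    Generates and validates stimulus schedules (revised
    60-stimulus/3-minute and legacy 360-stimulus designs), reads and
    segments 3-D hand-trajectory streams, detects movement onsets,
    derives per-trial reaction times, completion times, hand-path
    displacements and the commission index (ratio of X-trial displacement
    to the larger neighbouring-trial displacement), classifies trial
    events (omissions, partial omissions, multiple and premature
    reactions, commissions, inhibited commissions), summarises
    participants by medians, scores the 18-item SWAN rating scale into
    its inattention, hyperactivity and impulsivity factors, and reports
    predictor-by-factor correlations. A latent-trait cohort simulator
    with minimum-jerk hand kinematics makes the whole pipeline testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
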
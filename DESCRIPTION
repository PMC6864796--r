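Package: gaitevents
Title: Gait Event Detection and Stimulation Timing from Foot-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gait events (initial contact, full contact, heel off, toe
    off) from foot-worn six-axis inertial measurement units recorded during
    robot-assisted gait training, for triggering functional electrical
    stimulation. Implements arbitrary sensor-to-foot alignment via
    quiescence-anchored rotation-matrix estimation, a finite-state event
    detector with floating jerk thresholds, speed-adaptive angular-velocity
    thresholds and temporal safety gates, device profiles for exoskeleton and
    end-effector trainers, per-muscle stimulation scheduling from a gait-cycle
    timing chart, a synthetic gait-signal simulator with ground truth, and
    windowed detection-rate / type-1 error evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
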
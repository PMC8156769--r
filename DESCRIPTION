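Package: runfatigue
Title: IMU-Based Detection of Running-Induced Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting running-induced
    fatigue from body-worn inertial measurement units (IMUs). Generates
    synthetic track-running sessions (eight body segments at 240 Hz, 13 laps
    of 400 m with no/mild/heavy fatigue conditions), segments running gait
    from the sagittal pelvis velocity, normalizes strides to 150-point gait
    cycles, extracts a 157-feature catalogue (biomechanical, statistical and
    spatiotemporal features), applies one-lap moving-average smoothing and
    per-subject z-scoring, enumerates sensor-placement configurations, and
    evaluates each configuration with a nested leave-one-subject-out random
    forest using out-of-bag permutation importance to select the 12 best
    features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
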
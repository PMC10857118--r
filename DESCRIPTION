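Package: thighgait
Title: Gait Event Detection and Temporal Gait Parameters from a Single
    Thigh-Mounted IMU
Version: 0.1.0
Authors@R:
    person("thighgait", "developers", email = "thighgait@example.org",
           role = c("aut", "cre"))
Description: Detects the four essential gait events (initial contact, toe
    off, opposite initial contact, opposite toe off) from a single
    thigh-mounted inertial measurement unit using threshold and
    zero-crossing rules on band-pass filtered vertical acceleration and
    pitch angular velocity.  Computes the temporal gait parameters these
    events enable (stance, swing, symmetry index, single and double limb
    support, cadence), calibrates detection thresholds by grid search
    against reference events, scores detections against force-plate or
    simulated references, and ships a parametric gait-signal simulator
    with exact ground-truth event times so the whole pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
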
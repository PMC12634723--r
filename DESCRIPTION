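Package: handdex
Title: Multi-Sensor Hand Dexterity Assessment for the Minnesota Manual Dexterity Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated scoring of the Minnesota Manual Dexterity Test
    (MMDT) from three synchronized sensor streams: 8-channel surface
    electromyography (EMG) classified into hold/release motions with a
    log-linearized Gaussian mixture network (LLGMN), board-camera image
    sequences tracked with fixed-region HSV color thresholding and a per-hole
    event state machine, and forearm inertial measurement unit (IMU) traces
    summarized into angular-velocity and acceleration profiles. A declarative
    expert rulebase converts the measurements into textual clinical findings.
    Includes a fully synthetic session generator with ground-truth schedules
    for validation, agreement metrics against manual stopwatch timing, and a
    command-line session pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
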
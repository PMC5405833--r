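Package: gaitfes
Title: Reflexive Multichannel FES Gait Controller Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a sensor-driven, reflexive functional electrical
    stimulation (FES) controller for gait assistance without any hardware in
    the loop. Force-sensitive-resistor (FSR) insole and inertial signals are
    binarized with adaptive thresholds, a five-phase finite state machine
    detects gait events (heel strike, heel off, swing, terminal swing), and
    event impulses are convolved with second-order low-pass Butterworth
    impulse responses to shape per-muscle stimulation currents bounded by
    subject-specific minimum and maximum thresholds. Includes a seeded
    synthetic gait-signal generator with ground-truth phase labels, a
    kinematic analysis stage (heel-strike cycle segmentation, 101-point time
    normalization, range-of-motion statistics, corrected two-sample
    comparisons), and a command-line interface wiring the full control loop
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    zoo,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
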
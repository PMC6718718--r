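Package: emgrehab
Title: Simulated EMG-Controlled Knee-Exoskeleton Game Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation of a surface-EMG-driven knee-exoskeleton
    rehabilitation trainer: seeded synthetic 8-channel EMG envelopes, a
    streaming scalar Kalman filter with steady-state analysis, resting-bias /
    maximal-voluntary-EMG (MVE) calibration, proportional myoelectric mapping
    to knee angle with a cascaded PD position / PID velocity servo and a
    simulated joint plant, a headless adaptive-difficulty Flappy Bird training
    game, session orchestration with a configurable virtual subject, and the
    associated evaluation metrics (muscle activation level, block activation
    time, tracking RMSE, cross-correlation time lag, spectral attenuation,
    one-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
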
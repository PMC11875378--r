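Package: reachdnf
Title: Dynamic Neural Field Simulation of Selecting, Stopping and Switching Reaches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates action regulation in reaching movements by coupling
    dynamic neural fields (spatial sensory, expected outcome, reach cost, stop
    signal, pause, and reach planning fields) to finite-horizon stochastic
    optimal reach controllers through desirability-weighted policy mixing.
    Implements three pause-mechanism architectures for action switching, the
    decision-making, stop-signal and switch task protocols with adaptive
    +/-50 ms delay staircases, and a kinematic analysis pipeline (cubic
    smoothing splines, velocity-threshold reaction times, stop-probability
    curves, switch reaction times) applied identically to simulated and
    recorded joystick trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
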
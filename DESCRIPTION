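Package: marsbalance
Title: Simulation and Crash Prediction for a Disorienting Inverted-Pendulum
    Balancing Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a one-axis Multi-Axis Rotation System (MARS) analog
    programmed with inverted-pendulum dynamics, together with a synthetic
    disoriented-pilot controller that reproduces the statistical signatures of
    human balancing data (positional drift, 1-2 Hz joystick activity,
    destabilizing joystick deflections, crashes at the +/-60 degree
    boundaries).  Trials are segmented into crash-free episodes and converted
    into labeled sliding-window samples for time-in-advance crash prediction.
    Includes a self-contained neural-network engine (linear, multilayer
    perceptron, 1-D convolutional, LSTM/GRU and stacked recurrent
    classifiers), episode-grouped cross-validation with precision-at-fixed-
    recall model selection, and post-hoc crash analyses: misclassification
    stratified by angular position, destabilizing-deflection attribution,
    state-density maps, a bang-bang reachability recoverable region, and
    crash-savability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
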
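Package: neuromass
Title: Closed-Loop Modulation of Coupled Neural Mass Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates Wendling-type coupled neural mass models producing
    EEG-like alpha, delta and spiking regimes, and implements two closed-loop
    neurostimulation schemes around them: an incremental PID controller whose
    gains are selected offline by a binary-coded genetic algorithm (GA-PID),
    and a variant whose gains are additionally adapted online from the
    Jacobian of a radial-basis-function network plant estimator trained by
    gradient descent (GA-RBF-PID). Includes tracking-performance metrics
    (RMSE, settling time, overshoot) and named scenario presets that
    reproduce fixed-gain and mutated-gain experiments in alpha and delta
    oscillation regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
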
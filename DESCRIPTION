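Package: spikeplan
Title: Spiking Winner-Take-All Networks for Goal-Directed Planning and
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a recurrent winner-take-all spiking neural network
    that learns a world model of colour-action-feedback contingencies
    through spike-timing-dependent plasticity while simultaneously using
    that model for one-step planning as probabilistic inference.  Includes
    the entropy-based arbitration mechanism that decides between planning
    and exploration, a punishment-only exploration component implementing
    inhibition of return, the staircased visuomotor association task used
    to study the model's behaviour, and harnesses for behavioural
    aggregation (learning curves, planning-cycle reaction times),
    goal-switch analysis, Pearson-correlation model fitting and random
    parameter search.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
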
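Package: cdac
Title: Cost-Sensitive Bayesian Control Policies for Active Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solvers, approximations and a trial simulator for cost-sensitive
    Bayesian control of active sensing, modelled on gaze-contingent visual
    search. Implements the Context-Dependent Active Controller (C-DAC): exact
    value iteration on a discretized belief simplex for a behavioural cost
    that combines time, fixation-switch and error costs, together with a
    closed-form stopping-threshold bound, an information-maximization
    (Infomax) comparator, a myopic one-step approximation, and radial-basis
    -function and Gaussian-process value-function approximations. A stochastic
    trial simulator and analysis layer reproduce behavioural signatures such
    as confirmation bias and sensitivity of fixation switching to switch cost,
    in both foveal and graded peripheral-vision task environments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
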
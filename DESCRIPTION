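Package: bayesadapt
Title: Operating Characteristics of Bayesian Adaptive Trial Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-arm Bayesian adaptive clinical trial designs with
    interim analyses and estimates their frequentist operating characteristics
    (type I error, power, expected information at stopping) by Monte Carlo.
    Supports a time-to-event design monitored on the log hazard ratio through
    a normal-normal conjugate model, and a binary-outcome design with
    independent beta posteriors per arm, delayed follow-up, and
    posterior-predictive probability stopping rules for efficacy and
    futility. Includes a simulation-based calibration utility that tunes
    stopping boundaries to attain a target type I error, interim-schedule
    comparisons under common random numbers, and a YAML-driven command-line
    interface for reproducible design evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
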
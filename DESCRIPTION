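Package: peirs
Title: Prediction-Error-Induced Risk Seeking in Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how reward prediction errors shape risk
    preferences in value/risk bandit tasks. Implements the task generator
    (four approximately Gaussian reward arms crossing high/low mean with
    risky/safe spread, balanced pseudo-random pair schedules), twelve
    trial-by-trial learning and choice models built around the PEIRS rule
    (a tanh-gated contribution of the learned reward spread to action
    value, driven by the stimulus prediction error), maximum a posteriori
    fitting under Gaussian raw-space priors with BIC model comparison,
    cohort simulation with risk-preference summaries and traces, the
    behavioural analysis battery (inclusion filtering, accuracy traces,
    condition contrasts, emergence tests), and parameter/model recovery
    studies on fully synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
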
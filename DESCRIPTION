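Package: intergroupRL
Title: Reinforcement-Learning Models of Intergroup Impression Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models how trial-by-trial feedback from ingroup and outgroup
    members reshapes expectancies, social closeness and intergroup
    impressions in gain- and loss-framed social learning tasks. Implements
    Rescorla-Wagner learning models with group- and valence-specific
    learning rates, prediction-error-driven closeness-update models with
    exponential temporal discounting, per-participant maximum-likelihood
    fitting by multi-start bounded quasi-Newton optimisation, random-effects
    Bayesian model selection with exceedance probabilities, simulation-based
    parameter-recovery and model-identifiability validation, a synthetic
    study generator emulating the task structure, and the regression and
    moderation analyses linking fitted parameters to impression change.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
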
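Package: rlddmConflict
Title: Conflict Between Model-Based and Model-Free Control in the Two-Step
    Task via Hybrid Reinforcement-Learning Drift-Diffusion Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how conflict between model-based and
    model-free reinforcement-learning systems shapes human decisions in the
    two-step task. Implements the hybrid SARSA(lambda)/model-based learner
    with value decay and transition learning for both task variants, trial
    level between- and within-system conflict measures, a drift-diffusion
    decision layer whose drift rate, boundary separation and starting point
    are modulated by conflict, the Wiener first-passage-time likelihood, a
    two-stage hierarchical Bayesian fitting procedure with reduced
    single-pass variants, split R-hat convergence diagnostics, posterior
    summaries with a credible-interval significance rule, and a synthetic
    study generator with a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
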
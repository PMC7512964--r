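Package: divbayes
Title: General Bayesian Inference Under Alternative Divergence Criteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust Bayesian updating for misspecified models. Implements the
    general Bayesian (Gibbs) posterior whose inferential target is the
    parameter minimising a user-chosen statistical divergence between a
    parametric model and the data generating process: Kullback-Leibler,
    total variation, Hellinger, alpha, density-power (beta) and the
    two-parameter alpha-beta family. Provides the kernel density estimates
    (marginal and conditional) needed by the density-based empirical losses,
    an adaptive random-walk Metropolis sampler, closed-form conjugate
    updates for Gaussian linear models, leave-one-out posterior influence
    diagnostics, seeded simulators for epsilon-contaminated, heteroscedastic
    regression and AR-GARCH data, and configured experiment runners with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
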
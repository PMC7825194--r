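Package: ctsroi
Title: Model-Based Clinical Trial Simulation and Return-on-Investment
    Optimal Trial Design for Urate-Lowering Therapies
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <maintainer@example.com>
Description: A four-stage, seed-reproducible framework for Bayesian
    decision-theoretic design of a two-arm urate-lowering trial. Stage 1
    simulates trial response from linked pharmacokinetic/pharmacodynamic
    models (one- and two-compartment absorption kinetics driving an
    inhibitory indirect-response chain for uric acid turnover) together
    with a trial-execution model of imperfect dose implementation and
    Weibull treatment discontinuation. Stage 2 fits Beta prior
    distributions to the simulated response rates by moment matching and
    performs conjugate Beta-binomial updating over a grid of candidate
    sample sizes. Stage 3 maps posterior treatment response through a
    Markov cohort cost-effectiveness model to the payer's maximum
    reimbursement price. Stage 4 computes the sponsor's expected return
    on investment per design and sample size and locates the optimum.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
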
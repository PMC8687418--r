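Package: mssinfer
Title: Multiple Shooting Inference for Stochastic Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based parameter estimation for discretely observed
    stochastic chemical reaction networks.  Transition probabilities between
    successive measurements are approximated by Gaussian densities whose mean
    is the interval-wise reaction-rate ODE solution and whose covariance is an
    interval-wise linear noise approximation, giving a fully deterministic
    objective function (the extended multiple-shooting-for-stochastic-systems
    objective) that can be minimised with standard gradient-based optimisers.
    Includes exact Gillespie simulation for pseudo-data generation, partially
    observed and noisy-measurement variants of the objective, residual-based
    diagnostics of the Gaussian approximation, the exact analytic transition
    law of the immigration-death process as an oracle and reference estimator,
    and a replicated simulation-study harness with built-in benchmark models
    (immigration-death, prokaryotic auto-regulatory gene network,
    Lotka-Volterra).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
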
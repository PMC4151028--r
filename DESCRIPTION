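Package: balancesim
Title: Monte Carlo Simulation of Group Balance in Two-Arm Training Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how often randomly sampled and randomly assigned
    two-group experiments end up with groups that differ significantly in the
    composition of latent learner subpopulations (high/medium/low rates of
    improvement). Implements the sampling model (i.i.d. recruitment from a
    mixture of subpopulations), four assignment strategies (random,
    sequential coin-flip, stratified, matched pairs), a registry of
    chi-squared balance-test variants, a Monte Carlo engine estimating the
    unbalanced-sample rate with its standard error, and an exact
    combinatorial oracle that enumerates all group-composition outcomes to
    verify the Monte Carlo estimates and to calibrate under-specified test
    variants against published reference rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
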
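Package: duocomb
Title: Two-Stage Bayesian Adaptive Dose Finding for Dual-Agent Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design engine and simulator for two-stage phase I-II dose-finding
    trials of two-drug combinations with continuous doses. Stage I escalates
    along conditional maximum tolerated dose (MTD) distributions under the
    escalation-with-overdose-control (EWOC) principle and estimates an MTD
    curve from a reparameterized logistic dose-toxicity model. Stage II
    allocates patients along the estimated MTD curve by response-adaptive
    randomization and identifies the most efficacious tolerable combination,
    robustly borrowing stage-I efficacy data through an
    exchangeable/nonexchangeable (EXNEX) hierarchical mixture fitted by a
    meta-analytic-combined approach. Includes scenario calibration, Bernoulli
    outcome simulation, stopping rules for safety and futility, and an
    operating-characteristics engine over replicated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
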
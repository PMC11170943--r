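Package: tokensmdp
Title: State-Based Valuation and Motivation Analysis for Token
    Reinforcement Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling behaviour in stochastic token
    reinforcement tasks, in which choices earn or lose symbolic tokens
    that are exchanged for primary reward (juice) every four to six
    trials.  The package simulates task sessions with known ground
    truth, fits Rescorla-Wagner learning models to choice behaviour by
    maximum likelihood, converts mean cue-value curves into Bayesian
    cue-to-outcome transition probabilities, builds and solves the
    tabular Markov decision process whose state integrates token count,
    proximity to cash-out, task epoch and learning progress, and
    reproduces the motivation analyses that link state value to trial
    initiation times, choice latencies and trial aborts, including
    marginalisation over state features and exact small-sample group
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
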
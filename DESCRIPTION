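Package: signtrackr
Title: Dual-System Reinforcement Learning Simulation of Sign- and
    Goal-Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates Pavlovian autoshaping with a dual-system
    reinforcement learning agent that combines a Model-Based planner with
    a factored ("feature") Model-Free temporal-difference learner.
    Reproduces sign-tracker, goal-tracker and intermediate behavioural
    phenotypes from a single integration weight, their distinct reward
    prediction error (dopamine-like) signatures, and the effects of
    simulated flupentixol under systemic or intra-accumbens
    administration. Includes the task as a configurable episodic Markov
    decision process, four published model variants, experiment protocols
    with figure-level metrics, an NSGA-II multi-objective fitter with
    parameter-recovery diagnostics, synthetic target-curve generators,
    and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
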
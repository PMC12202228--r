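Package: aitbsim
Title: Bayesian Adaptive Trial Simulation for Accelerated iTBS Depression Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation engine and operating-characteristic calculator for a
    three-arm, sham-controlled Bayesian adaptive trial of accelerated
    intermittent theta-burst stimulation (aiTBS) for depression. Generates
    synthetic participant cohorts with MADRS change scores, pre-treatment
    attrition, session-completion counts and monthly follow-up trajectories;
    computes posterior probabilities of superiority between arms under
    non-informative priors; applies the design's interim decision rules
    (arm dropping, futility and success stopping) and final analysis;
    aggregates whole-trial simulations into power, type-I error, expected
    sample size and stopping probabilities; calibrates the final success
    threshold to a family-wise type-I error target; and implements the
    trial's clinical endpoint classification (response, remission, relapse,
    maintenance eligibility, intention-to-treat and per-protocol sets),
    stimulation-protocol arithmetic and titration validation, adverse-event
    comparison, and Benjamini-Hochberg adjustment with gatekeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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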
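Package: hoverbayes
Title: Bayesian Reasoning Performance and Mouse-Hover Transition Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing risk-communication experiments in which
    participants solve a Bayesian textbook task (positive predictive value
    of a binary test) presented as a natural-frequency or percentage tree
    whose nodes are revealed by mouse hover. Implements task-tree
    construction, posterior and sequential-posterior computation,
    strict-rounding correctness, log-relative-error and
    log-experience-deviation metrics, answer-strategy classification,
    hover-log parsing with validity filtering, dwell-time and bigram
    transition tables over the eight areas of interest, Hellinger-distance
    permutation tests, odds-ratio screening of discriminative transitions,
    association and regression reporting, a Markov-chain synthetic cohort
    generator, and a reproducible simulate/analyze/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
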
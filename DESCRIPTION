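Package: tplearn
Title: Simulation and Analysis of Temporal Perceptual Learning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing adaptive-staircase duration
    discrimination experiments used to study temporal perceptual learning.
    Provides a parametric two-interval forced-choice observer with
    scalar-timing (duration-proportional) Gaussian noise, lapses and
    session-wise learning dynamics; an exact one-up-three-down transformed
    up/down staircase with a coarse-to-fine step schedule and reversal
    bookkeeping; reversal-based threshold and Weber-fraction estimation with
    robust block, session and participant exclusion rules; and a learning
    index / transfer analysis across stimulus formats (empty and filled
    intervals) and standard durations. A full-study orchestrator simulates
    pre-test, training and post-test schedules for cohorts of observers and
    reduces trial-level logs to tidy participant- and group-level tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
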
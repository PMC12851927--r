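Package: cbgtimer
Title: Accumulator Timer Models and Population Analyses for Flexible Motor Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying flexible motor timing in the cortico-basal
    ganglia loop. Implements an accumulator ("timer") simulator with pause,
    slowdown and rewind perturbations and hazard-rate readouts; a zoo of
    threshold-linear rate-network integrator architectures with
    optogenetic-style perturbation protocols; and the accompanying
    behavioural and spike-train analysis pipeline: trial-history regression
    with cross-validated model selection, hierarchical bootstrap inference,
    hazard-rate estimation and sigmoid shift quantification, temporal
    warping, ramping characterization, targeted dimensionality reduction
    (cue, middle, ramp, execution and trial-history modes), population
    correlation matrices, two-dimensional vector fields, and k-nearest
    neighbour decoding of time-to-lick. A synthetic session generator with
    known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
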
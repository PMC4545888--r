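Package: covertsearch
Title: Multi-Area Stochastic Accumulator Model of Covert Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates and fits a multi-area leaky-competing-accumulator
    network for a covert visual search task in which a monkey locates an
    oriented target among distractors and reports its orientation by a
    left or right bar release. Six mutually inhibiting lateral
    intraparietal (LIP) units with distance-decaying inhibition, a pair of
    competing orientation-selective (IT) units, gated limb pre-motor (AIP)
    accumulators and thresholded motor units are integrated as a 20-equation
    stochastic system with Ornstein-Uhlenbeck input filtering. The package
    provides reaction-time and accuracy summaries, Gaussian-kernel firing
    rate estimation for spike trains, a composite neural/behavioral
    objective with quantile chi-square reaction-time fitting, simulated
    annealing plus Nelder-Mead optimization, and a synthetic spike/behavior
    dataset generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
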
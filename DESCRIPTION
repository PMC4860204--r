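Package: matreduce
Title: Reduction of Conductance-Based Neuron Models to Multi-Timescale
    Adaptive Threshold Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single-compartment conductance-based cortical neuron
    model with slow K+ currents (the muscarinic M-current and the
    Ca2+-activated afterhyperpolarization current), probes its instantaneous
    spike threshold by bisection, extracts spike-triggered ionic currents and
    post-spike threshold variations, and reduces the model to a
    multi-timescale adaptive threshold (MAT) neuron. The reduced model is
    fitted by maximizing the coincidence factor between predicted and
    reference spike trains, and its coding properties (f-I curves, noise
    sensitivity of the interspike interval, ISI variability and serial
    correlation) are computed analytically or by simulation. Includes
    Ornstein-Uhlenbeck and pulse stimulus generators, spike-train statistics,
    and plain-text serialization of traces, spike trains and fitted models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
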
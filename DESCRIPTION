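Package: vnresp
Title: Emotional-Speech Reward Learning in a Spiking Neurorobotic Loop
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale re-implementation of a virtual neurorobotic loop in
    which a simulated agent learns a two-choice visual-cue pointing task from
    spoken emotional rewards. Provides a synthetic emotional-speech generator,
    a RAPT-family pitch tracker (normalized cross-correlation candidates with
    dynamic-programming contour selection), utterance endpointing and a
    five-feature prosodic vector classified by an RBF-kernel support vector
    machine, confusion-matrix metrics, and a leaky integrate-and-fire network
    of four ten-neuron columns with reward-gated spike-timing-dependent
    plasticity driving the closed behavioral loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
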
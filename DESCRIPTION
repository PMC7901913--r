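Package: memstdp
Title: Memristive Synaptic Dynamics for Unsupervised STDP Learning in Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how the weight-update dynamics of memristive
    synapses (linear hard-bound, non-linear soft-bound, non-linear
    hard-bound) shape unsupervised learning in a two-layer spiking neural
    network trained with a simplified spike-timing-dependent plasticity
    rule. Provides the three dynamics families as continuous slope
    functions and discrete per-event updates, device figures of merit
    (resolution and non-linearity) with closed-form and quadrature
    evaluation, an event-driven leaky integrate-and-fire winner-take-all
    simulator, a training/evaluation pipeline (classification accuracy,
    weight contrast via 2-means clustering, training duration,
    efficiency), and a synthetic generator of MNIST-like digit images
    plus IDX-format input/output so real data can be substituted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    generics
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
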
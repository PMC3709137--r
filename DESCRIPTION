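Package: ratiolobe
Title: Spiking Antennal-Lobe Model for Ratiometric Chemosensor Transient Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the insect macroglomerular complex (MGC) of the
    antennal lobe as a discrete-time network of leaky integrate-and-fire
    neurons with exponential-decay synapses, integrated exactly on the grid
    by a time-constant correction. Builds probabilistic MGC connectomes that
    exhibit either fixed-point-attractor (winner-takes-all) or
    limit-cycle-attractor (winnerless competition) dynamics, adapts
    afferent and lateral inhibitory synapses with an asymmetric
    spike-timing-dependent plasticity rule, and decodes binary odour-blend
    concentration ratios from projection-neuron population trajectories with
    a nearest-mean-trajectory classifier swept over decision times. Includes
    generators for randomized ratio pulse trains and synthetic dual-channel
    surface-acoustic-wave resonator (SAWR) chemosensor transients, firing
    rate estimation with the discrete Gaussian (modified Bessel) kernel,
    PCA trajectory projection, and a fixed-point arithmetic verification
    mode for the exact-integration dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readr,
    patchwork
Config/testthat/edition: 3
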
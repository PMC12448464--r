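Package: dgsep
Title: Pattern Separation in Heterogeneous Dentate Gyrus Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for studying pattern separation
    in conductance-based spiking network models of the hippocampal dentate
    gyrus. Provides adaptive exponential integrate-and-fire (aEIF) neuron
    models for granule, basket, mossy and HIPP cells, stochastic
    population-of-models searches with electrophysiological validation,
    Poisson perforant-path input patterns with progressive morphing,
    a time-stepped network simulator with AMPA/NMDA/GABA-A synapses,
    spike-train similarity metrics, quantification of pattern separation
    and completion from rotated input-output similarity curves, and
    perturbation experiments (interneuron deletion, synaptic jitter and
    current noise, homogeneous versus heterogeneous comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
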
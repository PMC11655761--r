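Package: hebbnet
Title: Multi-Area Hebbian Rate Networks and Cell-Assembly Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates deep, brain-constrained rate-neuron networks: chains of
    cortical-like areas of excitatory and inhibitory graded-response cells wired
    by sparse, random, topographic projections, trained with a local
    Hebbian/anti-Hebbian (LTP/LTD) plasticity rule on binary stimulus patterns.
    Provides cell-assembly extraction by the gamma-threshold membership rule,
    kernel/halo partitioning, pairwise overlap and quasi-orthogonality analysis,
    and working-memory experiment protocols (ignition, persistent reverberation,
    and superposition of co-active assemblies), with tidy accessors and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
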
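Package: axocouple
Title: Propagation-Signal Neurons and Putative Synaptic Couplings from
    Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies single neurons in multi-electrode array (MEA)
    recordings of cultured networks by their axonal action-potential
    propagation signals (cohorts of electrodes firing with fixed
    sub-millisecond delays), and detects short-latency, putatively synaptic
    couplings between those neurons and spikes elsewhere on the array using
    windowed cross-correlograms with configurable acceptance criteria.
    Includes statistical validation controls (two-sample Kolmogorov-Smirnov
    comparisons of coupled versus randomly sampled spike amplitudes,
    inter-spike-interval-preserving shuffles with chance-coupling ratios),
    directed connectivity graphs with cross-condition comparison, spike
    detection from raw extracellular voltage, and a ground-truth simulator
    for benchmarking recovery of planted propagation cohorts and couplings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
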
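Package: adathresh
Title: Adaptive Spike Threshold Neurons and State-Robust Information Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how an adaptive
    spike threshold shapes single-neuron stimulus encoding. Provides
    exponential integrate-and-fire neurons with adaptive or fixed spike
    thresholds and a Hodgkin-Huxley point-conductance model, a stochastic
    100-to-1 feedforward synaptic network with rate- and pattern-encoded
    presynaptic stimuli, trace-level spike-threshold metrology for
    intracellular voltage sweeps, a mutual-information pipeline with shuffle
    plus Panzeri-Treves bias correction, state-aware decoding and robustness
    indices with stimulus-centered or response-centered time references, and
    a generator of synthetic in-vitro-like recording sessions with known
    threshold-versus-EPSP-slope ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
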
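Package: dgntrace
Title: Unsupervised Discriminator-Generator Networks for Single-Molecule
    Fluorescence Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts hidden fluorophore-count state paths from noisy
    single-molecule fluorescence intensity time traces with an unsupervised
    discriminator-generator network (DGN): a bidirectional LSTM encoder maps
    each trace to a per-frame posterior over fluorophore counts, and a
    bidirectional LSTM decoder reconstructs the trace from that posterior, so
    the pair can be trained on unlabelled experimental traces. Training blends
    the reconstruction loss with an annealed cross-entropy on synthetic
    labelled traces. Includes a calibrated trace simulator (shot noise,
    Gaussian noise, fluorophore blinking, adjusted signal-to-noise targeting),
    photobleaching step counting and population distributions, state
    occupancies, transition rates and exponential dwell-time fits with
    bootstrap summaries, and a Gaussian-emission hidden Markov model baseline
    with Viterbi decoding for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mclust,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
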
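Package: gammel
Title: Detection, Parameterization and Decoding of Theta-Nested Gamma Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for the analysis of transient gamma
    oscillatory events ("gamma elements") nested in the hippocampal theta
    rhythm. Multichannel local field potentials are decomposed into band
    composites by ensemble empirical mode decomposition, converted to
    current source density, and scanned cycle-by-cycle for patches of
    elevated gamma power in Morlet wavelet spectrograms. Each detected
    element is parameterized by three gamma features (amplitude, frequency,
    theta phase) and three features of its host theta cycle (amplitude,
    frequency, asymmetry). Downstream tools decode navigation behavior from
    single elements with class-balanced boosted trees, decompose
    feature-behavior mutual information into unique, redundant and
    synergistic parts, and simulate a theta-driven quadratic
    integrate-and-fire excitatory-inhibitory network that reproduces
    gamma-element diversity. A synthetic-data module generates behavior
    tracks and recordings with known burst statistics so that every stage
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rpart,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
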
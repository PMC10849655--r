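Package: natcont
Title: Natural Continuation: Scoring Neural Encoding Models Against
    Naturalistic Courtship Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating candidate neural encoding models of
    Drosophila courtship song history against naturalistic behavior.
    Implements a multiplicative-adaptation (MA) dynamical encoder and a
    matched linear-nonlinear (LN) encoder, fitting of both models to
    block-stimulus calcium response traces, simulation of artificial
    neural population recordings over courtship sessions, ridge-readout
    scoring of walking-speed predictions over repeated session-level
    train/test splits (the Natural Continuation procedure), and
    characterization analyses: response-entropy song information,
    population PCA with a behavioral sign convention, power-law scaling
    of inter-trajectory distances, accumulation correlations, and
    reservoir-style linear readouts of target waveforms. A synthetic-data
    module generates semi-Markov song sequences, noisy block responses,
    and full synthetic courtship studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
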
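Package: wellddm
Title: Quantum Square-Well Models of Arousal in Perceptual Decision-Making
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models two-alternative forced-choice (2AFC) perceptual decisions
    with a one-dimensional quantum particle in a two-square-well potential.
    Each well represents one response option; the probability mass the
    wavefunction accumulates inside a well (its mean integration efficiency)
    is mapped to the drift rate of a standard drift-diffusion model, which
    then yields choice probabilities and response-time distributions. Two
    arousal mechanisms are implemented: sampling of bound eigenstates through
    a spectral selection window, and scaling of the Matrix Numerov kinetic
    operator, the latter producing smooth inverted-U (Yerkes-Dodson)
    performance curves. Includes a parameter-sharing fitting pipeline
    (fixed barrier energy, shared landscape, per-coherence well depth,
    per-participant kinetic scale) with a seeded particle-swarm optimizer,
    a synthetic drift-rate table generator for parameter-recovery studies,
    YAML configuration, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
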
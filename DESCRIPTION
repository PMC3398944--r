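Package: degraph
Title: Degradation Graphs for Reconstructing Proteolytic Processes from
    Mass Spectrometry Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs proteolytic processes from time series of
    centroided mass spectra. Builds a degradation graph (peptides as
    nodes, exo- and endoproteolytic reactions as edges, internal
    cleavages represented by pseudo-nodes) from peak lists and a seed
    peptide by alternating peptide-mass-fingerprint verification and
    extension, derives the first-order mass-action ODE system of the
    graph, estimates reaction rates, per-peptide intensity
    transformation factors and the seed's initial concentration by
    bounded weighted nonlinear least squares, and selects the
    best-supported subgraph with a two-component score (mean Pearson
    correlation of predicted versus observed traces, and conserved
    signal variability) driven by an iterative leaf-trimming beam
    search. A seeded simulator emits ground-truthed noisy peak-list
    time series so the whole inference chain is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    minpack.lm,
    deSolve,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
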
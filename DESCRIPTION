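Package: mycoassembly
Title: Null-Model Inference of Fungal Community Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the processes that assemble host-associated
    fungal communities from OTU abundance tables. Implements the beta nearest
    taxon index (bNTI) against a tip-shuffling phylogenetic null, the
    Raup-Crick index (RCI) against richness-preserving taxonomic nulls
    (presence/occupancy and abundance variants), and the joint five-way
    classification of sample pairs into selection, dispersal and stochastic
    assembly classes. Also provides dissimilarity-overlap curve (DOC)
    universality analysis with bootstrap change-point detection,
    richness-free turnover partitioning (Simpson/Sorensen/nestedness),
    community Fst, compositional preprocessing (rarefaction, zero-imputed
    centred log-ratio, Hellinger), sequential PERMANOVA, Mantel tests, beta
    dispersion, principal coordinates, a stochasticity-versus-community-size
    mixed model, proportionality-based co-abundance networks, and a
    random-forest community-age delay protocol. A seeded generator simulates
    communities assembled under drift, selection and dispersal regimes on a
    compartment-by-week-by-treatment field design so every inference can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    lme4,
    lmerTest,
    igraph,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
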
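Package: profclust
Title: Comparative Clustering of Protein Co-Fractionation Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates protein interaction datasets derived from
    co-fractionation (complexome profiling) experiments across multiple
    species and biological systems.  Interactor profiles are compared with
    an orthology-aware rank-biased overlap score, reciprocal top hits are
    assembled into a combined hypernetwork, and Markov clustering yields
    superclusters that are split into per-complexome subclusters with
    fraction-clustered scores, coherence-based filtering, reference-complex
    annotation and maximum-matching-ratio evaluation.  A synthetic
    complexome generator with planted conserved and taxon-specific
    complexes supports end-to-end benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
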
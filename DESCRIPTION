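Package: spongenet
Title: Competing Endogenous RNA Network Inference from Count Matrices and Sequences
Version: 0.1.0
Authors@R: person("spongenet", "maintainers", email = "maintainers@spongenet.dev", role = c("aut", "cre"))
Description: An end-to-end, offline pipeline for competing endogenous RNA
    (ceRNA) network inference in two-group bulk RNA-seq designs. Provides
    class-aware differential expression on pooled counts (Fisher's exact
    test, CPM and SRPBM normalisation), dual miRNA-target prediction
    (canonical seed-site scanning with a 0-100 context-style score, and
    local duplex alignment with an additive hybridisation-energy model)
    intersected under configurable cut-offs, direction-consistent
    lncRNA/circRNA-miRNA-mRNA network assembly with cross-sponge
    integration and hub ranking, hypergeometric term enrichment against
    user-supplied GMT collections, and a synthetic-data generator that
    plants known fold changes and sponge-miRNA-mRNA triads so the whole
    pipeline is testable without access to restricted sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
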
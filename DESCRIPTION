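Package: metapull
Title: Metabolite-to-Protein Virtual Pulldown and Network Module Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds protein-protein interaction network modules around
    proteins associated with discriminant metabolites ("virtual pulldowns").
    Provides multi-omics quality control for metabolite intensity tables
    (missingness filtering, median scaling, half-minimum imputation, natural
    log transform) and amplicon count tables (prevalence filtering, centered
    log-ratio transform), PCA-based multivariate outlier detection, resolution
    of metabolites to seed proteins through an association table, first-order
    subnetwork extraction from a confidence-weighted interactome with
    over-connected-node pruning, size capping and overlap-based merging,
    one-sided Fisher over-representation analysis with Benjamini-Hochberg
    correction, classification of networks into disease-core and exploratory
    sets, and cross-network annotation summaries. A synthetic-data generator
    produces interactomes with planted modules, metabolite-protein association
    tables, gene sets and four-group omics matrices for benchmarking the
    whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
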
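Package: coexdiff
Title: Differential Co-Expression Network Analysis for Transcriptome
    Cytotoxicity Screens
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for two-condition transcriptome cytotoxicity
    studies: RPKM normalization and fold-change/FDR screening of differentially
    expressed genes from a read-count matrix, gene-set over-representation with
    Fisher's exact and chi-square tests and the enrichment ratio Re, ontology
    (GO-style) true-path annotation propagation and GO-tree construction,
    gene-act and pathway-act networks on a background relation graph,
    per-condition Pearson co-expression networks with degree and k-core
    differential topology to rank key regulatory genes, 2^-ddCt qPCR relative
    quantification with RNA-seq concordance, and four-parameter logistic IC50
    fitting. Ships a seeded synthetic-data generator (negative-binomial counts
    with planted fold changes and condition-specific co-expression modules,
    ontologies, relation graphs, Ct tables, dose-response curves) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
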
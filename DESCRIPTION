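Package: droughtMAPKKK
Title: Maize MAPKKK Family Identification and Drought-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the mitogen-activated protein kinase kinase
    kinase (MAPKKK) gene family of maize under drought stress. Identifies
    family members among candidate proteins by a pairwise-identity threshold
    with a minimum-hit-count rule, assigns Raf, MEKK and ZIK subfamilies by
    degenerate kinase-domain motif scanning, calls differentially expressed
    genes from replicate FPKM tables with a fold-change and p-value rule,
    summarises three-tissue overlap and direction concordance, performs
    hypergeometric singular enrichment analysis with FDR control and
    PageMan-style signed Wilcoxon category z-scores, scores pathway-level
    co-expression between regulators and pathway genes on a soft-threshold
    network, and links delta-delta-Ct qPCR expression to biomass drought
    tolerance indices by Pearson correlation. Ships synthetic-data
    generators with known planted truth so every stage is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    SummarizedExperiment,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
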
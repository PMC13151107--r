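Package: pathdisturb
Title: Single-Sample Pathway Disturbance Scoring from Germline and Somatic Variants
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies biological pathway disturbance in individual cancer
    samples by integrating variant deleteriousness (Phred-scaled CADD scores)
    with gene essentiality (DepMap CRISPR dependency probabilities) into
    gene-level impact scores, mapping those scores onto GO and KEGG gene sets
    with a modified gene set enrichment statistic under a gene-permutation
    null, and reporting per-pathway disturbance scores, cohort-level
    phenotypic convergence, and significant-pathway subnetworks. Includes an
    optional Gaussian-mixture expression gate that zeroes the impact of
    unexpressed genes, and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
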
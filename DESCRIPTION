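Package: owlsets
Title: Dynamic Gene Set Construction by OWL 2 EL Reasoning over the Gene Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps controlled-vocabulary terms to sets of Gene Ontology classes
    by answering description-logic queries with an OWL 2 EL completion-rule
    reasoner, using a hierarchy of bespoke grouping object properties (property
    chains and reflexivity emulate disjunction within the EL profile). The
    resulting term sets drive a file-based mapping pipeline that compares
    automated against manual mappings, and feed rank-based over-representation
    analysis of expression data: direct-annotation gene sets, Gini-index tissue
    signatures, Wilcoxon rank-sum enrichment scores with signed Z-scores,
    Jaccard overlap, and clustered Z-score matrices for heat maps. Includes
    deterministic synthetic fixtures (toy ontologies, random EL ontologies,
    expression matrices with planted signatures) so the full pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
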
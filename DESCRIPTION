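Package: mirphen
Title: Phenome-Guided Prioritization of Disease MicroRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a functionally related microRNA network from the
    statistical significance of target-gene overlap (one-sided Fisher exact
    test with Benjamini-Hochberg correction), scores every network microRNA
    for a query disease phenotype with a cumulative hypergeometric module
    statistic over phenotypically similar diseases, and evaluates the
    resulting rankings with leave-one-out cross-validation (four variants),
    ROC/AUC summaries and permutation-based coherence tests. Includes a
    seeded synthetic-data generator with planted cluster/block structure so
    the whole pipeline can be exercised without external downloads, and a
    command-line driver for the main workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
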
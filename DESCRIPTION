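Package: litnet
Title: Gene Co-Occurrence Networks and Disease-Gene Ranking from Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds human gene-gene interaction networks from biomedical
    abstract text by dictionary named-entity recognition of gene symbols and
    Gene Ontology term names, extracts a nine-dimensional co-occurrence
    feature vector per gene pair over abstract, sentence, and semantic text
    levels, classifies pairs with rare-event weighted (kernel) logistic
    regression, and prioritizes candidate disease genes by centrality ranking
    of seed-anchored subnetworks. Includes bootstrap hyperparameter tuning,
    ROC/precision-recall evaluation, precision-at-n benchmarking, a
    synthetic-corpus generator with planted interaction graphs, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
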
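Package: dupsplice
Title: Gene Duplication and Alternative Splicing Stratified by Duplication Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interrogates the relationship between gene duplication and
    alternative splicing (AS) across duplication ages. Qualifies paralog
    pairs at a sweep of protein-identity criteria, clusters them into gene
    families by single linkage, classifies genes into AS/no-AS families and
    singletons (A_F, N_F, MIXED_F, A_S, N_S), and computes family-size
    stratified AS proportions and isoform counts, Pearson chi-squared
    enrichment tests, Ka/Ks, protein-length, domain-count and Gene Ontology
    category summaries, and EST-based expression profiles. Ships a
    synthetic-data generator with planted family structure, age-dependent
    AS probabilities and closed-form planted expectations so every pipeline
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    broom,
    knitr,
    rmarkdown
Config/testthat/edition: 3
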
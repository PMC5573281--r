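Package: burdenscope
Title: Rare-Variant Burden Testing and Candidate-Gene Prioritization for
    Behavioral-Phenotype Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for case-only rare-variant analysis
    of small phenotype-stratified exome cohorts. Annotated variant calls are
    reduced to the novel, predicted-damaging set (region class, caller FILTER
    flags, known-database membership, CADD phred threshold); per-gene burden
    is tested against reference-population counts with a one-sided
    two-proportion test and Benjamini-Hochberg control; candidate genes are
    prioritized with expression and functional-annotation evidence scores
    computed as random-forest vote proportions against literature-anchored
    training sets; hits are quantified for enrichment in known genes and
    projected onto a weighted interaction network to extract the module
    anchored by training positives. A synthetic-data generator emulates every
    input with known ground truth so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
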
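Package: begland
Title: Gland Phenotype Diversity and Clonal Ancestry in Barrett's Esophagus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies Barrett's esophagus glands into the five canonical
    phenotypes from lineage-marker expression profiles, quantifies per-specimen
    phenotypic richness and Shannon diversity with bootstrap
    sampling-sufficiency analysis and nonparametric group comparisons, and
    infers clonal ancestry between phenotypically distinct glands from shared
    somatic mitochondrial DNA mutations after stroma subtraction and
    polymorphism filtering. A forward simulator of gland-fission clonal
    expansion with neutral mitochondrial mutation accrual and phenotype
    transitions generates synthetic cohorts with known genealogy so that every
    stage of the analysis can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
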
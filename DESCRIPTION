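Package: branmet
Title: Comparative Rice Bran Metabolomics Across Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of non-targeted metabolomics
    feature tables from rice (Oryza sativa) bran. Implements median scaling
    of relative abundances, cross-cultivar Z-score screening for
    cultivar-discriminating metabolites, a fold-style pathway enrichment
    score, linkage of discriminating metabolites to rice biosynthetic genes
    curated from the OryzaCyc / Plant Metabolic Network database, class-count
    reporting with ordination summaries, and a synthetic-data generator
    emulating a 17-cultivar by ~450-metabolite panel so the full pipeline is
    testable without access to raw instrument data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
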
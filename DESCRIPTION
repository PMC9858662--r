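Package: trnaome
Title: Comparative Analysis of tRNA Gene Repertoires, Copy-Number
    Variation and tRNA-Derived Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for comparative tRNAome analysis
    across the three domains of life. Parses tRNAscan-SE tabular
    annotations into per-locus tables, builds per-genome censuses of
    tRNA gene copy number, anticodon repertoire, intron content and
    pseudogenes, classifies anticodon-amino-acid combinations by their
    cross-domain pervasiveness, computes gene-density and genome-size
    scaling statistics, summarises intraspecific copy-number variation,
    and types tRNA-derived small-RNA fragments (tRF-1/tRF-3/tRF-5)
    against mature-tRNA models. A synthetic-cohort generator emulates
    domain-specific genome annotations so every pipeline stage is
    testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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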
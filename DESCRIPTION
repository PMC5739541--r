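Package: hictad
Title: Banded Hi-C Contact Maps and Directionality-Based Domain Boundary
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Post-alignment processing of Hi-C read pairs (duplicate
    removal, read-orientation classification, short-span genomic
    contamination filtering), construction of banded fixed-width contact
    matrices, vanilla-coverage normalization with histogram-equalized
    display, coverage-weighted directionality scores and a heuristic
    caller for topologically associating domain (TAD) boundaries,
    boundary-feature colocalization statistics (metaplots,
    fold-enrichment fractions, interval matching, four-way
    domain-termination sorts), and exact-word (k-mer) enrichment analysis
    of boundary sequences.  A synthetic-data generator with planted
    domain structure, restriction-site deserts, contaminating genomic
    read pairs, ChIP-like peaks and planted sequence motifs lets the full
    pipeline be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
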
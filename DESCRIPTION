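Package: enhancerscan
Title: Detection of Conserved Clusters of Pigmentation Transcription
    Factor Binding Sites in Upstream Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans 1500-nucleotide upstream regions of pigmentation genes for
    IUPAC consensus binding sites of six melanocyte transcription factors
    (CREB, FOXD3, LEF1, MITF, POU3F2, USF1) under a percent-dissimilarity
    threshold, collapses matrix-level matches into per-factor site classes,
    and detects candidate enhancer modules as the top-ranked ~200-nucleotide
    windows containing sites for two or more distinct factors. Also computes
    ortholog percent-identity matrices and range summaries for coat-color
    gene families, renders color-coded module tracks (SVG, text, ggplot2),
    and generates synthetic upstream regions with planted site clusters and
    protein families at controlled divergence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
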
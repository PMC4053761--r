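Package: chromspread
Title: Spreading of Histone H3K4 Methylation from Promoters and Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how histone H3 lysine 4 (H3K4) methylation is focused
    at gene promoters and enhancer cores, and how it spreads into gene bodies
    and enhancer shores when an H3K4 demethylase is depleted. Implements
    strand-aware ChIP-seq tag density computation (RPBM), TSS-centered and
    length-scaled metagene profiles, the promoter-versus-gene-body spreading
    index (SI) and its enhancer core/shore analogue, empirical cumulative
    distribution comparisons with a two-sample Kolmogorov-Smirnov test,
    sliding-window enrichment of differentially expressed or bivalent genes
    along ranked gene lists, promoter co-occupancy and bivalency calls, RPKM
    quantification with threshold-based differential-expression calling, and a
    seeded synthetic-data generator with ground truth so the whole pipeline is
    testable without sequencing data.
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
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
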
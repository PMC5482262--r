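Package: symits2
Title: Within-Sample OTU Clustering and Metacommunity Analysis for
    Symbiodinium ITS2 Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An amplicon-analysis toolkit for ITS2 metabarcoding of
    Symbiodinium in reef corals. Turns paired-end reads into quality-
    controlled amplicons, builds operational taxonomic units (OTUs) under
    three strategies (100% identity, 97% identity across samples, and 97%
    identity within samples with merge-by-identical-representative),
    assigns taxonomy by Needleman-Wunsch global alignment against a named
    reference database, and computes community statistics (Bray-Curtis
    dissimilarity, PERMANOVA, multivariate dispersion as a measure of
    symbiotic flexibility) and bipartite host-symbiont association
    networks for dominant, abundant, and background symbiont niches.
    Includes a synthetic metacommunity generator with ground truth, so
    the behaviour of each clustering strategy on communities with
    intragenomic rDNA variation can be tested offline.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
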
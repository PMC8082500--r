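Package: triadnet
Title: Multi-Tissue Co-Expression Networks, Regulatory Triad Motifs and
    Gene Importance Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for multi-tissue transcriptome network biology:
    median-absolute-deviation gene filtering, weighted gene co-expression
    network construction (soft thresholding, topological overlap, module
    detection and merging, eigengenes, gene significance, module membership,
    intramodular connectivity, network topology concepts, key-module and
    hub-gene calls), tissue-specificity index (tau) and fuzzy c-means
    expression-pattern clustering, assembly of mixed gene regulatory networks
    from position-weight-matrix promoter scans and miRNA target records,
    a three-node (triad) motif census with degree-preserving randomized null
    ensembles, Z scores and the length-normalized triad significance profile,
    composite node/edge/motif importance scores with extraction of the top
    regulating-mutual complex, and cross-dataset replication testing. Includes
    a synthetic-data generator with planted modules, tissue-specific genes and
    regulatory triads so the whole pipeline is testable end to end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
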
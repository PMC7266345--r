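Package: samclust
Title: Consensus Clustering and Cell-Type Enrichment Analysis for Meristem Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of cell-type-specific transcriptomes from
    FACS-sorted shoot apical meristem (SAM) populations: group-wise calling of
    cell-type-enriched genes from pairwise contrast tables, six-sector Venn
    classification, consensus clustering of log2 fold-change profiles by a
    resampled k-means ensemble with personalized-PageRank edge filtering and
    Infomap community detection, hierarchical time-course clustering,
    hypergeometric gene-set enrichment with over-representation filters, and
    cluster/cell-type overlap summaries. Includes a synthetic-data generator
    that plants cell-type-enriched genes and response clusters so the whole
    pipeline can be exercised and validated without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    limma,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    fgsea,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
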
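Package: methrank
Title: Ranking Epigenetically Regulated Genes from Paired Promoter
    Methylation and Expression Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate epigenetically regulated genes from paired
    CpG-site methylation and gene-expression measurements across a panel of
    cell lines. The protocol reduces the methylation data in two steps
    (genomic-proximity grouping followed by spectral clustering of
    methylation profiles with automatic bandwidth and cluster-count
    selection by a compactness criterion), associates each cluster's
    representative profile with gene probe sets inside a fixed base-pair
    window, and ranks genes by the quality of a constrained decreasing
    sigmoid fit of expression on methylation, with significance from
    permutation testing. Includes a synthetic-panel generator emulating the
    structure such studies assume, so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
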
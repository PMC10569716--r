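Package: scregion
Title: Regional Enrichment and Cis-Regulatory Statistics for Multi-Region
    Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for multi-region single-nucleus RNA and
    ATAC atlases: per-cell k-nearest-neighbour regional enrichment scores
    (lochNESS) with a region-bias gene regression, Jensen-Shannon regional
    specificity and barcode-contamination screening, nucleus- and
    cluster-level quality-control rules, metacell-based peak-gene
    cis-regulatory inference with differential-accessibility marker calling,
    and transcription-factor activity-sign classification.  A synthetic-data
    module generates paired multi-region RNA/ATAC datasets with planted
    ground truth so that every stage can be verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Matrix,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
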
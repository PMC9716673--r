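Package: imprintscreen
Title: Pharmacogenomic Association Screens for Imprinted Gene Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association analysis linking gene-level copy number, expression,
    and gene-region-averaged DNA methylation of imprinted genes to cancer drug
    response (log10 IC50), in the style of pancancer cell-line pharmacogenomic
    screens. Implements methylation probe filtering and gene-region averaging
    for 450K-style arrays, cytoband-based chromosomal segment assignment with
    curated and correlation-driven merging, Spearman/Pearson correlation
    screens (pancancer and stratified by cancer category), Benjamini-Hochberg
    FDR and a conservative segment-grouped max-p FDR procedure, a Beat-AML-style
    validation stage (expression versus ex vivo response plus a two-group
    log-rank test), and a synthetic cohort generator with planted effects for
    calibration and power studies.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
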
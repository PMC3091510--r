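Package: preservr
Title: Cross-Tissue Co-Expression Module Preservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted gene co-expression network analysis across tissues:
    unsigned soft-thresholded adjacency, topological overlap, dendrogram
    module detection, module eigengenes and module membership (kME),
    permutation-based module preservation Zsummary statistics with the
    2/5/10 interpretation, combined module-membership hub-gene selection
    with hypergeometric overlap tests, heritability group comparisons and
    marker-gene correlations. Includes a factor-model generator of
    multi-tissue expression data with planted, partially preserved
    modules, and a staged pipeline runner with machine-readable
    provenance. Tibble-first interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
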
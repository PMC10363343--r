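Package: statemapper
Title: Mapper Graphs and Mesoscale Statistics for Multichannel Brain
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds Mapper graphs (topological data analysis) from labeled
    multichannel electrophysiological time series and compares experimental
    paradigms through mesoscale graph invariants.  Time points are embedded
    in two dimensions (PCA or t-SNE), covered by overlapping rectangular
    bins, clustered per bin by single-linkage agglomeration in the original
    channel space, and joined into a nerve graph whose nodes are labeled by
    the paradigm dominating their member time points.  Node centrality
    (degree, eigenvector, betweenness, closeness) and Newman modularity are
    summarised per paradigm and compared across subjects with a
    Shapiro-Wilk-gated choice between the paired t-test and a paired
    sign-flip permutation test, with Bonferroni correction across a sweep of
    Mapper parameter triples.  Includes a hidden-state simulator of
    paradigm-dependent state-recurrence structure and a packaged worked
    example of per-subject closeness-centrality pairs.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
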
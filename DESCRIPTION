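Package: efnet
Title: Evolutionary Analysis of Elementary Functionome Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds age-annotated bipartite networks linking elementary
    functional loop prototypes to SCOP domain superfamilies, derives their
    time-directed unimodal projections, discretizes network growth into
    evolutionary events, and computes per-event scale-free diagnostics
    (log-log regression exponents, discrete power-law maximum likelihood
    fits with Kolmogorov-Smirnov bootstrap tests) and modularity indices
    (Newman-Girvan modularity under age and community partitions, quality
    index, clustering coefficient, fast-greedy and walktrap communities).
    Includes a synthetic bipartite network generator with founder-wave age
    structure and preferential loop attachment, waterfall and accumulation
    visualizations, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    igraph,
    pracma,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
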
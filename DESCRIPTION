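Package: eegnets
Title: Fast-Scale EEG Functional Networks from Sliding-Window Rank Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds time-resolved functional networks from multichannel EEG by
    sliding-window zero-lag Spearman correlation, binarizes them under a
    fixed-number-of-links (or fixed-threshold) criterion, extracts local and
    global graph measures (degree, clustering coefficient, betweenness,
    average path length), and compares two experimental conditions electrode
    by electrode with a rank test under a Bonferroni plus multi-density
    robustness criterion. Includes Erdos-Renyi null baselines, a lag
    correlation diagnostic, and a synthetic 10-20-montage EEG generator with
    spatially decaying correlations and injectable condition effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    signal,
    stats,
    tools,
    utils,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
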
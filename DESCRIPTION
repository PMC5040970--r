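Package: netprep
Title: Pre-Processing and Co-Expression Network Inference for Large Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for building genome-scale gene co-expression networks
    from large, heterogeneous microarray compendia assembled from public
    repositories. Covers duplicate-array removal, array-level quality control
    (scale factors, spike-in presence, RLE/NUSE from a median-polish probe-level
    model), MAS-style summarization and normalization (trimmed-mean scaling,
    log2, mean centering, quantile normalization), interquartile-range gene
    filtering with two data-driven threshold selectors (derivative-minimum and
    histogram-mode), probe-set to gene collapsing, keyword classification of
    submissions into tissue- and process-specific datasets, Pearson-correlation
    and B-spline mutual-information network construction with permutation
    significance testing and data-processing-inequality pruning, and union
    network assembly. Includes a seeded synthetic-compendium generator with
    planted ground truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
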
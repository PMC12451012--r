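Package: nichescan
Title: Characterizing a Precancerous Niche from Grouped Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing a precancerous tissue niche from grouped
    single-cell or spatial transcriptomic expression data. Implements
    reference-baseline copy-number inference from smoothed relative expression
    (expression floor, clipping, per-chromosome moving average, BaseMax/BaseMin
    baseline subtraction), Gini-index ranking of group-specific secreted
    ligands combined with one-vs-rest Wilcoxon over-expression tests,
    gene-signature scoring with region-restricted ligand-signature Spearman
    correlation, and quadrant-gated quantification of multiplex
    immunohistochemistry intensity tables. A seeded negative-binomial
    simulator with planted copy-number segments, group-specific ligands and
    ligand-signature co-expression provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
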
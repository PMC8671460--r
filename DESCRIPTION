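Package: repurposr
Title: Drug-Repurposing Screen Analysis for Cancer Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pooled viability drug-repurposing screens
    (PRISM-style log fold-change matrices) on cancer cell-line panels.
    Provides calibrated sensitivity-threshold selection via Youden's index,
    active-compound and mechanism-of-action landscape summaries, rank-correlation
    clustering and repeated t-SNE embeddings with a consistency rule for
    assigning putative mechanisms to non-oncology compounds, two-class
    differential killing-activity comparison, transcriptomic biomarker
    discovery (empirical-Bayes moderated t-statistics, Pearson shortlisting,
    gene-signature Z-scores, hypergeometric over-representation), and a
    from-scratch weighted Kolmogorov-Smirnov gene set enrichment analysis with
    permutation-based normalized scores and false discovery rates. A synthetic
    screen generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Rtsne,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
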
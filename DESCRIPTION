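Package: crossvote
Title: Cross-Study Comparison of Voting-Based Classifiers for Gene
    Expression Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for comparing binary-outcome classifiers across
    gene-expression studies under class imbalance. Implements
    rank-based cross-study feature selection (per-study signal-to-noise
    ranking, normalized mean rank, permutation significance with
    Benjamini-Hochberg FDR control), importance-ranked forward model
    building over seven classification methods (random forest, logistic
    regression, four support vector machine kernels, and a single
    hidden-layer neural network), a two-level majority-voting
    meta-classifier, balanced-accuracy evaluation, and a repeated
    downsampled binomial test for pairwise classifier comparison on
    imbalanced test sets. A synthetic multi-study generator with planted
    outcome signal and platform distortions makes the full internal,
    same-platform, and cross-platform validation experiments runnable
    end to end without any external data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
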
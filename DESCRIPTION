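Package: nullmargins
Title: Margin-Constrained Null Models for Presence-Absence Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Significance testing of patterns in binary presence-absence
    matrices under two families of margin-sum constraints: the fixed-fixed
    model, which preserves row and column sums exactly and is sampled with
    the sequential swap Markov chain, and the Rasch maximum-entropy model,
    which preserves margin sums in expectation through independent
    logistic cell probabilities. Includes checkerboard-unit counting,
    pairwise Fisher-exact co-occurrence screening, K-means clustering
    error, a randomization-test engine with empirical p-values, swap-chain
    convergence diagnostics, exhaustive enumeration of small
    margin-constrained matrix classes, and synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
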
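Package: faaknn
Title: Functional Outlier Detection by Archetype Projection Ensembles and
    k-Nearest-Neighbour Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects outlying curves in (possibly clustered) functional data
    by projecting the curves into mixture-coefficient subspaces obtained from
    functional archetype analysis fitted for a range of archetype counts,
    scoring every curve by the summed Euclidean distance to its k nearest
    neighbours in each subspace, and averaging the scores over the (p, k)
    ensemble.  Continuous scores can be hardened to binary labels with an
    upper boxplot fence.  Includes a synthetic-data generator for clustered
    Gaussian-process curves with five outlier families (amplitude, vertical
    shift, horizontal shift, shape and isolated outliers) and a replicate
    harness that summarises true- and false-positive detection rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
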
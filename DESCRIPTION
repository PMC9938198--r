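Package: rnafrag
Title: Exterior-Loop Partitioning and Fragment-Wise RNA Secondary Structure
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives exterior-loop labels and independent fragments
    (i-fragments) from RNA secondary structures, trains a windowed
    convolutional/recurrent sequence labeler to predict those labels from
    sequence alone, and uses predicted labels to partition a long RNA, fold
    each fragment independently with a pluggable predictor, and assemble the
    complete structure. Includes dot-bracket/CT/BPSEQ structure I/O, base-,
    segment- and pair-level evaluation metrics with bootstrap standard
    errors, and a seeded synthetic structure generator with controllable
    fragment architecture and label noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
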
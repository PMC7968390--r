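Package: sonnetgaze
Title: Lexical Surface Features and Predictive Modeling of Eye Movements in Poetry Reading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes seven lexical surface features (word length, log
    frequency, orthographic neighborhood density, higher-frequency
    neighbors, mean Levenshtein orthographic dissimilarity,
    consonant-vowel quotient, and a sonority score) for word types
    against a reference corpus; aggregates fixation-level eye-tracking
    interest-area reports into word-level reading measures (first
    fixation duration, gaze duration, re-reading time, total reading
    time, fixation probability) with explicit skip handling; and
    compares ordinary least squares, a small neural network, and a
    bagged-tree ensemble in predicting those measures from the
    standardized features via repeated 90/10 holdout validation, with
    variance-based total-effect feature importances. Includes a
    synthetic-data generator with known ground truth so every pipeline
    stage is testable without proprietary corpora or participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    withr,
    ggplot2,
    generics,
    nnet,
    randomForest,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
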
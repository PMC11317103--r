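Package: foodsig
Title: Passive Food-Safety Surveillance from Restaurant Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and grades food-safety signals in consumer restaurant
    reviews. Implements a passive-surveillance workflow over
    sentiment-labelled review streams: near-duplicate screening with lexical
    diversity and similarity metrics (type-token ratio, Jaccard similarity,
    bigram overlap), a chi-square goodness-of-fit screen that separates
    chance fluctuation in monthly hygiene complaints from genuine temporal
    clustering, keyword-lexicon classification of negative reviews into
    eight inspection-checklist sub-aspects, a Causality Assessment Index
    (ratio of negative to positive hygiene reviews), a weighted Severity
    Assessment Score with five public-health risk grades, category-level
    reporting, and privacy-jittered GeoJSON export. Includes a seeded
    synthetic-suburb generator with exact ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    igraph,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
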
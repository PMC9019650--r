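Package: agenarr
Title: Diachronic Framing Analysis of Aging Narratives in Historical Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how the framing of older adults (age-based terms such as
    "elderly" versus role-based terms such as "grandmother") has shifted across
    decades of a historical corpus. Extracts collocates within a six-word
    lexical span around target terms, filters them by Mutual Information,
    scores them with a two-rater 1-5 valence lexicon, aggregates
    frequency-weighted narrative scores per decade, fits and compares linear
    decade trends between framings, and contrasts topic-level positivity
    across centuries with seeded Latent Dirichlet Allocation and a two-way
    mixed ANOVA. Includes a synthetic-corpus generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
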
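Package: afprs
Title: Polygenic Risk Scores for Atrial Fibrillation Occurrence and
    Post-Cardioversion Recurrence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Case-control and recurrence analysis of a small panel of
    atrial-fibrillation-associated single-nucleotide variants.  Builds a
    population-tailored unweighted polygenic risk score with a directional
    allele-flipping rule (flip when the listed risk allele is protective at
    p < 0.1), dichotomizes it at a strict threshold, and fits the
    univariate (Woolf odds ratios, chi-squared tests) and multivariate
    logistic models that relate genotypes and the score to arrhythmia
    occurrence and to recurrence after direct current cardioversion.
    Includes a seeded synthetic-cohort generator (Hardy-Weinberg genotypes,
    logistic outcome models, table-matched covariate marginals) so the full
    pipeline can be exercised and validated by parameter recovery when
    individual-level study data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
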
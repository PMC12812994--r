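Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pharmacovigilance toolkit for FAERS-style
    spontaneous reporting data. Ingests quarterly ASCII ("$"-delimited) or CSV
    report bundles, deduplicates multi-version cases, tags primary-suspect
    reports for target drugs via a synonym lexicon, and maps MedDRA preferred
    terms to system organ classes. Computes four disproportionality statistics
    per drug-event pair (reporting odds ratio with Woolf intervals,
    proportional reporting ratio with chi-square, the BCPNN information
    component with its lower credibility bound, and the empirical-Bayes
    Gamma-Poisson shrinker EBGM/EB05), applies the four-algorithm signal
    criterion, and ranks signals by frequency and strength. Includes
    sex-stratified subgroup analysis with volcano-plot coordinates, Weibull
    time-to-onset modelling with hazard-type classification, Kaplan-Meier and
    log-rank comparisons, a concomitant-drug sensitivity re-analysis, and a
    seeded synthetic report generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
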
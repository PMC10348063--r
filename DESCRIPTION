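Package: jpvsignal
Title: Disproportionality Signal Detection for JADER-Style Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection in
    spontaneous adverse-event report databases distributed in the JADER
    three-table schema (demographics, drug, reaction). Ingests and links
    the tables with the standard exclusions (missing sex or age,
    duplicate rows, non-suspected drug roles), classifies reactions by
    MedDRA preferred-term sets, builds case-level two-by-two contingency
    tables, and computes reporting odds ratios with Woolf confidence
    intervals and Bayesian confidence propagation neural network (BCPNN)
    information components with credibility intervals, applying the dual
    signal criterion (lower ROR bound > 1 and lower IC bound > 0).
    Includes time-to-onset binning with outcome tallies, sex and age
    stratification, and a synthetic report generator with known ground
    truth so the whole pipeline can be validated without the real
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
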
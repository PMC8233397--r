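Package: pvprr
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance disproportionality analysis of
    spontaneous adverse-event reports. Reads simplified FAERS-style quarterly
    extracts (DEMO/DRUG/REAC) and flat CSV report tables, normalizes verbatim
    drug names to active ingredients by regular-expression cleanup, alias
    dictionaries and Levenshtein clustering, maps reaction strings to a
    preferred-term vocabulary, and computes proportional reporting ratios
    (PRR) with log-scale confidence intervals and three-criterion signal
    flags for every drug-event pair. Includes a logistic-regression
    change-in-estimate check for demographic confounding, Friedman rank tests
    across drug groups blocked by adverse events, principal component
    analysis of drug ADE profiles, and a synthetic report generator with
    known ground truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
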
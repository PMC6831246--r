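Package: pvsignal
Title: Pharmacovigilance Signal Detection from Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for disproportionality-based signal detection in spontaneous
    adverse-event reporting data. Reads individual case safety report (ICSR)
    tables, applies the standard inclusion filters used in national
    pharmacovigilance analyses (WHO-UMC causality, initial reports of suspected
    drugs, complete demographics), explodes reports into drug-event pairs,
    builds 2x2 contingency tables against an all-other-drugs comparator, and
    computes the proportional reporting ratio (PRR), reporting odds ratio
    (ROR), Yates-corrected chi-square, and the Bayesian confidence propagation
    neural network information component (IC) with Monte-Carlo credible
    intervals. Signals are called by the classical triple criterion and
    classified as expected or unexpected against drug-label references;
    sex- and age-adjusted reporting odds ratios are estimated by case/non-case
    logistic regression. Includes a seeded synthetic ICSR generator with
    controllable signal strength and confounding for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
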
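Package: bodecomp
Title: Threefold Blinder-Oaxaca Decomposition of Binary Outcome Disparities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying group disparities in a binary health
    outcome from survey data: weighted frequency and prevalence tables,
    Pearson chi-square screening, survey-weighted logistic regression with
    odds-ratio tables, and a threefold Blinder-Oaxaca decomposition of the
    gap in prevalence between two groups into endowment, coefficient and
    interaction components, with detailed per-covariate-level
    contributions and stratified bootstrap confidence intervals. Includes
    a synthetic-data generator with a known group-specific logit
    data-generating process and a Monte-Carlo oracle for the true
    decomposition components, so every stage can be validated without
    restricted survey data, and a configuration-driven pipeline producing
    reproducible table artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
Config/testthat/edition: 3
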
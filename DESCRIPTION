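Package: pleiomed
Title: Family-Based Pleiotropy and Mediation Analysis of a SNP on Lipids and Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based pleiotropy analysis of a single biallelic
    variant on quantitative lipid traits and type 2 diabetes status. Implements
    additive-model genotype coding, Hardy-Weinberg equilibrium testing,
    adjusted linear (log-lipid) and logistic (disease) association models with
    percent-change effect reporting, subgroup analyses, and counterfactual
    mediation decomposition of the genotype-disease effect through a lipid
    mediator: natural direct and indirect effects on the odds-ratio scale,
    proportion mediated, family-resampling bootstrap confidence intervals,
    and a Monte-Carlo potential-outcome oracle. A family-structured cohort
    simulator with Mendelian transmission provides fully reproducible synthetic
    data for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
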
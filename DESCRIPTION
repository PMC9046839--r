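Package: gxematch
Title: Gene-Environment Additive Interaction Analysis for Frequency-Matched
    Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the design and analysis of 1:c frequency-matched
    case-control studies of gene-environment interaction with diallelic
    markers. Implements the matched-design minimum sample-size formula,
    case selection and seeded frequency matching on age group and sex,
    Hardy-Weinberg equilibrium and case-control chi-square tests, SNP
    inheritance-model coding (dominant, recessive, codominant, additive),
    maximum-likelihood unconditional logistic regression with Wald
    inference, and additive-scale interaction measures (relative excess
    risk due to interaction, attributable proportion, synergy index) with
    delta-method and stratified-bootstrap confidence intervals, together
    with a seeded synthetic cohort generator and a fixture builder that
    reconstructs individual-level records from published genotype count
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
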
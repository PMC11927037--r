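Package: mrtriage
Title: Drug-Target Mendelian Randomization with Mediation and Druggability Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide drug-target Mendelian randomization (MR) screens that
    chain summary-data-based MR (SMR) with the HEIDI linkage test, two-sample
    MR validation with sensitivity analyses (IVW, MR-Egger, MR-Egger bootstrap,
    weighted median), multivariable MR direct effects, product-of-coefficients
    mediation with distribution-of-product confidence intervals, stage-wise
    Bonferroni filtering, and cross-database druggability annotation with
    causal-direction compatibility triage. Ships a summary-statistics
    simulator with a known causal graph (instruments -> gene expression ->
    mediator -> outcome) so every stage is testable end to end without
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
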
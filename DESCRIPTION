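Package: grsMR
Title: One-Sample Mendelian Randomization with Weighted Genetic Risk
    Scores and Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for one-sample Mendelian randomization of modifiable
    risk factors on an incident time-to-event outcome. Builds weighted
    genetic risk scores from GWAS weight files and genotype dosages
    (genome-wide significance filtering, LD pruning, allele
    harmonization, mean imputation), runs two-stage instrumental-variable
    analysis with Cox proportional-hazards and logistic second stages,
    and provides MR-Egger, weighted-median and inverse-variance-weighted
    sensitivity estimators together with instrument-strength F
    diagnostics. A parallel observational Cox scan supports
    Bonferroni-corrected exposure screening, quintile dose-response
    analysis with inverse-variance-weighted trend fitting, and
    reverse-causation sensitivity exclusions. A synthetic-cohort
    generator with known ground-truth causal effects (LD blocks via a
    Gaussian copula, latent confounding, directional pleiotropy,
    exponential proportional-hazards event times) makes every stage
    testable without access to restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
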
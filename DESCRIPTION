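Package: immunoQG
Title: Quantitative Genetics of Induced Immune Traits in Aquaculture
    Breeding Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pedigree-based animal-model analysis of immune-response traits
    measured in paternal half-sib nested breeding designs, as used to assess
    the selection potential of induced HSP70 levels in farmed red abalone.
    Builds the numerator relationship matrix from a pedigree, fits
    single-trait linear mixed models by restricted maximum likelihood
    (average-information updates with expectation-maximisation fallback),
    tests fixed effects by Wald F and variance components by boundary
    log-likelihood-ratio tests, and converts variance components into
    heritability, repeatability, mean-standardised coefficients of additive
    and residual variation, and predicted response to truncation selection.
    Includes a synthetic-data generator that emulates the nested full-sib
    design with repeated measures, and fixed-effects ANOVA utilities
    (Levene and Shapiro-Wilk checks, least-squares means with sequential
    Bonferroni correction) for the phenotypic comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    car,
    emmeans,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
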
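Package: acutetox
Title: Acute Toxicity Analysis with Probit LC50, Species Sensitivity
    Distributions and Inter-Chemical Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for acute aquatic-toxicity assessment of
    heavy metals: probit-method LC50 estimation from dose-mortality tables
    (empirical-probit least squares or binomial maximum likelihood, with
    delta-method or Fieller confidence intervals), screening of
    heterogeneous literature toxicity records, species mean acute value
    (SMAV) aggregation by geometric mean, species sensitivity distribution
    (SSD) ranking with rank/(N+1) cumulative probabilities and HC5
    estimation, and pairwise inter-chemical toxicity extrapolation models
    with leave-one-out cross-validation and external validation. Includes
    a seeded synthetic-data generator emulating the statistical structure
    of ECOTOX-style data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
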
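Package: powerlda
Title: Power-Law Limiting Dilution Assay Analysis with Cooperative Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of limiting dilution assays (LDA) under cooperative or
    competitive clonogenic growth. Generalizes the single-hit Poisson model
    by a power law, lambda = p * S^b, fitted as a binomial regression of the
    well failure fraction with a log-log link. Provides clonogenic activity
    estimates with Fieller-type confidence intervals by confidence-band
    inversion, treatment survival fractions with confidence intervals from
    combined 83.5% activity intervals, nested-model comparison against the
    classical linear (b = 1) model by likelihood-ratio test and AIC,
    replicate pooling with a binomial expectation-range diagnostic, and a
    seeded simulator of LDA count tables for coverage and design studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
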
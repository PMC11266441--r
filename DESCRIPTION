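Package: enviroGP
Title: Environment-Aware Machine-Learning Genomic Prediction for
    Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Genomic prediction of maize grain yield across
    multi-environment trials using gradient boosting on engineered
    environmental features (envirotyping) and genomic relationship
    matrices. Implements the full workflow: single-trial mixed models
    producing hybrid BLUEs with coefficient-of-variation and Cullis
    generalized-heritability diagnostics; a 90-feature environmental
    matrix from 30-minute weather series, crop-model covariates
    compressed by SVD, lagged historical yield, soil assays, binned
    coordinates and management; marker quality control (MAF filter, LD
    pruning) and VanRaden additive / Vitezica dominance relationship
    matrices; additive (G+E) and Kronecker-product (GEI) feature
    constructions with a factorized truncated SVD that never
    materializes the Kronecker product; sparse-testing cross-validation
    schemes (CV2, CV1, CV0) with Pearson accuracy, Coincidence Index,
    tester-overlap and dependent-correlation comparison tests; and a
    seeded synthetic-study generator emulating a parent-by-tester
    hybrid trial network so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    xgboost,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
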
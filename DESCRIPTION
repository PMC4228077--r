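Package: phenoimpute
Title: Missing-Value Imputation and Imputability Assessment for Mixed-Type Phenomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: K-nearest-neighbour imputation for subjects-by-variables tables that
    mix continuous, ordinal, binary and multi-class categorical (nominal)
    variables, as found in high-dimensional clinical phenotype ("phenomic")
    studies. Provides four imputers -- by nearest variables (KNN-V, using a
    mixed-type correlation matrix of Spearman, biserial, polyserial, polychoric,
    phi and Cramer's V measures), by nearest subjects (KNN-S, using Gower
    distances), and two hybrids combining both with a globally estimated (KNN-H)
    or correlation-adaptive (KNN-A) weight -- plus a mean-imputation baseline and
    a pluggable-imputer interface. Includes a per-cell imputability measure (IM)
    that flags missing values which cannot be imputed reliably, a self-training
    selection (STS) scheme that picks the best imputer per data type from the
    data at hand, normalized RMSE/PFC evaluation utilities, three block-correlated
    simulation scenarios for benchmarking, and an end-to-end application
    guideline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
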
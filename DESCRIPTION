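Package: phenolink
Title: Linking Self-Report Mental Health Measures to Brain
    Imaging-Derived Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for population-scale studies that
    relate self-report mental-health questionnaires to brain
    imaging-derived phenotypes (IDPs). Provides ordinal questionnaire
    scoring (RDS-4, PHQ-9, GAD-7, N-12, probable depression status),
    matched case-control cohort construction with
    exploratory/confirmatory splits, confound residualization,
    nearest-neighbour imputation and per-modality PCA, canonical
    correlation analysis with permutation inference, averaged-UV
    loadings and out-of-sample replication, equipercentile score
    linking, univariate effect sizes by modality, and ICC(A,1)
    test-retest reliability. A synthetic-data generator emulates the
    statistical structure of such studies so the whole pipeline is
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
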
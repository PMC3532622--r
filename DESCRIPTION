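Package: msisig
Title: Microsatellite-Instability Gene-Expression Signatures for Colorectal
    Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Develops and applies nearest-centroid gene-expression signatures
    for the microsatellite-instability (MSI) phenotype of colorectal tumours.
    Provides repeated cross-validated t-test gene selection, a single-sample
    MSI index defined as the difference of cosine correlations to MSI and MSS
    centroids, dual-threshold MSS / MSI-like / MSI classification, ROC and
    threshold optimisation, per-sample mutation-frequency analysis over a
    fixed gene panel, Kaplan-Meier / Cox survival analysis of signature
    strata, and a synthetic-cohort generator that emulates the statistical
    structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
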
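Package: stgee
Title: Spatially Robust Differential Expression Testing for Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression testing between pathology regions in
    spatial transcriptomics count data, accounting for spatial correlation
    among spots. Implements cluster-robust Poisson estimating-equation tests
    (robust Wald, generalized score test, and the Independent GEE special
    case with heteroskedasticity-robust standard errors), alongside the
    Wilcoxon rank-sum and two-sample z-test baselines; spatial K-means
    working clusters; 10x Visium input handling with quality-control and
    highly-variable-gene selection; genome-wide scans with FDR/FWER
    correction, QQ diagnostics and sparsity stratification; and a Poisson
    log-normal spatial simulator with a Type I error / power benchmark
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
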
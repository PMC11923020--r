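Package: latentdiff
Title: Observed Versus Latent Standardized Mean Differences for Ordinal Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how measurement error distorts observed group
    comparisons on item-based questionnaire scales. Provides closed-form
    classical-test-theory attenuation results, a synthetic two-group ordinal
    data generator with known latent structure, threshold and polychoric
    correlation estimation, an invariance-constrained two-group ordinal
    one-factor model (diagonally weighted or unweighted least squares) with
    latent mean comparison and McDonald's omega, discrepancy statistics
    between observed (sum-score) and latent standardized mean differences
    with a one-tailed z test, and random-effects meta-analysis of per-scale
    discrepancies.
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
    metafor,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
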
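Package: stockflows
Title: Sex-Specific Bilateral Migration Flow Estimation from Migrant Stock Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates five-year bilateral international migration flows by sex
    from bilateral migrant-stock tables and demographic components (populations,
    births, deaths, sex ratio at birth). Implements six estimation methods:
    stock differencing with negative differences dropped or reversed as return
    flows, a rates-based proportional allocation of the global flow total, and
    three demographic-accounting methods (open and closed systems with a
    diagonal-maximising quasi-independent imputation, and a pseudo-Bayesian
    weighted combination with an independent imputation). Includes a
    move-type decomposition (outward, return, transit), validation metrics
    against reported flow statistics, and a demographically consistent
    synthetic-world generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
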
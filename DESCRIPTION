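Package: icefalcon
Title: Inference About Causation Through Examination of Familial Confounding in Twin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether an exposure-outcome association observed in
    twin-pair data is consistent with causation or with confounding by familial
    (genetic and shared-environment) factors. Implements the ICE FALCON three-model
    coefficient-change procedure on double-entered twin pairs using generalized
    estimating equations with an exchangeable working correlation and robust
    sandwich variances, formal Wald tests of the changes in regression coefficients
    via stacked estimating equations or a cluster bootstrap, covariate-adjusted
    within-pair correlations with Fisher's z comparison of monozygotic and dizygotic
    pairs, an ACE variance-components generator of synthetic twin cohorts with
    closed-form population coefficients, a replication harness for bias, mean square
    error, size and power of the change statistics, and an end-to-end analysis
    pipeline producing descriptive, regression and ICE FALCON tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
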
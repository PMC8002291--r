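Package: seapscreen
Title: Reporter-Gene High-Throughput Screen Analysis with Dual-Read Hit
    Calling and Delta-Delta-Ct Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for plate-based reporter-gene
    (secreted alkaline phosphatase, SEAP) compound screens in the style used
    for inflammation-focused phenotypic screening. Provides assay-quality
    statistics (intra- and inter-assay coefficient of variation, Z'-factor,
    dilution-series linearity), per-plate mean + k*SD hit calling with a
    dual-read concordance rule and cytotoxicity counterscreen flagging,
    delta-delta-Ct (2^-ddCt) relative quantification with fold-suppression
    ratios and a normality/variance-driven statistical test selector, and a
    seeded, truth-labelled synthetic-data generator so that the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    withr,
    jsonlite,
    stats,
    utils,
    car,
    multcomp,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
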
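Package: surveildq
Title: Data Quality and Early-Warning Concordance for Syndromic Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the completeness and timeliness of routinely
    collected primary-health-care encounter data affect an early-warning
    system for influenza-like-illness outbreaks. Provides a synthetic
    generator of municipality-level encounter registries with realistic
    reporting delays, batched monthly uploads and late amendments; a
    composite Data Quality Index (DQI) computed on 8-week rolling windows;
    EARS-C2 aberration detection on weekly counts; and concordance analysis
    of outbreak warnings between real-time snapshots and the backfilled
    gold-standard dataset, stratified by data-quality level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
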
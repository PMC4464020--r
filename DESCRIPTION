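Package: regqc
Title: Data-Quality Indicators and Monitoring Reports for Population-Based
    Maternal-Newborn Health Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the battery of enrollment, pregnancy-outcome,
    mortality, key-variable and process indicators used to monitor data
    quality in prospective population-based maternal and newborn health
    registries, flags cluster- and site-level results against a catalogue
    of acceptable values, runs range/skip/cross-form edit checks, draws
    re-keying samples, and assembles monthly monitoring reports. Includes
    a seeded multi-cluster registry simulator with an orthogonal
    defect-injection layer so every indicator and check can be exercised
    end-to-end without access to any real registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    methods,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
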
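Package: zoopint
Title: Multi-Survey Zooplankton Monitoring Data Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for integrating long-term zooplankton monitoring data
    collected by multiple surveys with heterogeneous protocols. Standardizes
    per-survey catch tables into a common long format keyed by sample,
    harmonizes taxonomic resolution across surveys and through time by
    rolling counts up to the lowest rank counted everywhere (with an
    alternative non-exclusive taxa-of-interest mode), corrects
    introduced-species time lags, converts conductivity to practical
    salinity (PSS-78 with the low-salinity extension), computes flowmeter
    volumes, catch per unit effort, and carbon biomass, flags taxa
    undersampled by a gear via matched-sample comparison, summarizes
    subsampling precision under Poisson counting, validates that
    harmonization conserves total catch, and simulates multi-survey
    monitoring programs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    purrr,
    tibble,
    rlang,
    stringr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
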
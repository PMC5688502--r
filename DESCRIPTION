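Package: equilist
Title: Equity Analysis of Child Health Intervention Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing within-country inequality in maternal,
    newborn and child health intervention coverage. From wealth-quintile
    disaggregated coverage surveys the package computes inequality ratios
    (top-quintile over national coverage), resolves proxy and backup
    interventions for indicators not measured in surveys, and runs a
    deterministic coverage-to-mortality impact model to estimate deaths
    averted when national coverage is raised to the level of the richest
    quintile. Includes a multi-country aggregator (full and limited
    analyses), a per-country single-intervention ranking ("equity tool"),
    and a seeded synthetic survey generator so the whole pipeline is
    testable without survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    jsonlite,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
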
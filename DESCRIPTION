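Package: nbudget
Title: Nitrogen Budgets for Ridge-Furrow Forage Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling plant-soil-atmosphere nitrogen budgets from
    multi-year factorial field trials of mulched ridge-furrow forage systems.
    Computes soil inorganic nitrogen stocks from layered bulk-density and
    concentration profiles, nitrous oxide fluxes from closed static-chamber
    headspace series with trapezoidal integration to seasonal totals, plant
    nitrogen accumulation from per-cut organ samples, and the apparent
    nitrogen balance and apparent nitrogen loss rate per treatment-year,
    with surplus/deficit classification. Includes factorial analysis of
    variance with normality and variance-homogeneity prechecks and protected
    least-significant-difference letter displays, plus a deterministic
    synthetic trial generator so the full pipeline is testable end to end
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
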
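Package: sustainaswap
Title: Modeling Nutrient and Environmental Effects of Sustainable Food Swaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the replacement of a reference food (such as beef) with an
    environmentally sustainable alternative matched on energy or protein
    content. Computes net nutrient deltas per serve, including estimated
    absorbed iron under heme/non-heme bioavailability assumptions, and
    environmental footprints (greenhouse gas, land use, acidifying and
    eutrophying emissions, stress-weighted water) per serve and accumulated
    over a 270-day pregnancy, with a passenger-vehicle distance equivalence
    for greenhouse gas reductions. Applies swap scenarios to cohorts of
    individual daily nutrient intakes to model shifts in intake distributions
    and compliance with Nutrient Reference Values, and generates synthetic
    cohorts with log-normal intake marginals coupled by a Gaussian copula for
    fully reproducible analyses when individual-level dietary data are
    restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
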
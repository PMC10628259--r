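Package: thirty30
Title: Spatial Prioritization and Evaluation of 30x30 Protected-Area Expansion Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for systematic conservation planning toward the 30x30 target
    (protecting 30 percent of land by 2030). Builds climate-informed per-species
    feature layers from current and future habitat-suitability surfaces
    ("win-win" weighting of climate refugia), ranks land by greedy marginal-loss
    removal in the core-area Zonation family under hierarchical protected-area
    masks and optional per-subregion coordination, and evaluates the resulting
    selections with a modified Species Protection Index with log-linear
    rarity-scaled targets, weighted-endemism capture, and trade-offs against a
    reference scenario. Includes a seeded synthetic-landscape generator so the
    full pipeline is testable without geospatial downloads, plus scenario
    comparison via overlap classes, rank correlations, and non-metric
    multidimensional scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    picante,
    sp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
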
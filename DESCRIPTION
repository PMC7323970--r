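Package: agrisuit
Title: Agro-Climatic Crop Suitability Modelling Under Climate Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling agro-climatic crop suitability from daily
    gridded weather and district yield statistics. Derives eight agronomic
    predictors (growing-season and seasonal rainfall sums, rainfall
    variability, diurnal temperature range, seasonal temperature means and
    topsoil organic carbon) from daily precipitation and min/max temperature
    grids, labels four ordinal suitability classes (limited, marginal,
    moderate, optimal) from yield percentiles, fits a four-class
    gradient-boosted tree classifier with cross-validated tuning, evaluates
    it with confusion-matrix metrics (overall accuracy, kappa,
    pairwise-average multiclass AUC and eleven per-class statistics),
    projects suitability under additive general-circulation-model climate
    deltas, and aggregates single-crop maps into multi-crop rank-sum scores
    and area-change tables. A seeded synthetic-data module emulates the
    required inputs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
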
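Package: wetsdm
Title: Ensemble Species Distribution Models for Wetland Plants on Synthetic Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of an ensemble species distribution
    modelling (SDM) workflow for wetland plant species: derivation of bespoke
    hydro-climatic covariates (potential evapotranspiration, water balance,
    growing degree days, water-and-wetness probability index, topographic
    wetness index, D8-accumulated upstream anthropogenic land cover, coastal
    salt influence), a plot preparation protocol (filtering, spatial thinning,
    minimum-presence rule, per-technique absence sampling, calibration split),
    variance-inflation-factor covariate screening, a TSS-weighted GLM/GAM/BRT
    ensemble with permutation variable importance, and spatial plus ecological
    niche validation (maxTSS binarisation, true positive rate against
    independent occurrences, evaluation-strip response curves, modelled
    indicator values, and Spearman tests against ordinal ecological indicator
    values). All stages are exercised on synthetic landscapes and species with
    known niche optima so every result can be scored against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
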
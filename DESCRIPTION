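Package: denclim
Title: Hierarchical Gaussian Process Models of Denning Phenology and Climate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian analysis of hibernation (denning) phenology in relation
    to daily climate, built around two models: a three-level hierarchical
    Gaussian-process regression of event-aligned temperature trajectories with
    variance partitioning, and a time-varying-coefficient ("distributed lag")
    model of denning dates driven by daily temperature and snow depth with
    Gaussian-process priors on the coefficient functions.  Includes a
    synthetic-data generator for multi-park daily climate series and denning
    event dates, readers and validators for phenology and station climate
    tables, nearest-station assignment, event-aligned lag-window construction,
    loess snow-trajectory summaries, exhaustive windowed-average linear mixed
    model comparison via exact-refit leave-one-out cross-validated log
    predictive density, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    tidyr,
    rlang,
    jsonlite,
    lme4,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
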
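Package: eetofleet
Title: Explore-Exploit Strategies and Disturbance Response in Fishing Fleets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies explore-exploit trade-off (EETO) strategies from
    vessel-movement tracks and estimates their consequences for trip revenue
    during a spatial fishery closure. The pipeline cleans hourly position
    records, classifies fishing activity with a random-forest ensemble,
    discretizes fishing grounds on a grid, computes choice entropy and patch
    residence time per vessel, builds a business-as-usual counterfactual of
    trip revenue from a vessel fixed-effects model, and fits mixed-effects
    and growing-window regressions of revenue deviance on strategy metrics.
    A seeded synthetic-fleet generator emulates the structure of confidential
    vessel-monitoring, observer and logbook data so that every stage is
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    geosphere,
    ranger,
    lme4,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    randomForest,
    withr
Config/testthat/edition: 3
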
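Package: vitisim
Title: Daily Carbon Balance and Berry Sugar Simulation for Grapevine Canopies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the seasonal carbon balance of a grapevine at a daily
    time step: canopy gross photosynthesis from a rectangular-hyperbola leaf
    light response integrated through a Beer-Lambert canopy, organ maintenance
    and growth respiration with an Arrhenius temperature response, and the
    conversion of the daily CO2 balance to dry matter.  Downstream tools fit
    a linear regression of berry sugar content (degrees Brix) on cumulative
    dry matter, predict sugar trajectories under cluster-thinning scenarios,
    and report goodness-of-fit statistics (R2, MAE, RRMSE, PBIAS).  A seeded
    synthetic-season generator produces weather, canopy and observation
    tables with the statistical structure of a temperate vineyard trial so
    that every stage of the pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
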
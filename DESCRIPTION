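Package: twinstest
Title: Twin-Birth Quasi-Experiment for Detecting Parity-Dependent Fertility Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the twin-birth quasi-experiment used in historical
    demography to test whether a population practised parity-dependent
    fertility control. Provides a monthly-step microsimulator of marital
    fertility histories (natural fertility, target-family-size controllers,
    or mixtures), construction of per-delivery analysis tables from family
    birth histories, least-squares estimators of the twin effect on total
    births, surviving children and post-twin birth intervals (parametric and
    fully interacted variants, with a parity-interaction test), closed-form
    expected twin effects under no control and complete control, mixture
    bounds on the population share of controllers, and data-quality
    diagnostics (same-sex twin ratio, familial twin repetition, twinning
    correlates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
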
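Package: beedemog
Title: Seasonal Elasticity Analysis of Honeybee Colony Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Age-structured Leslie matrix model of a honeybee (Apis
    mellifera) colony with brood, nurse and forager stages,
    Gompertz-Makeham worker mortality, and food-limited brood
    production.  Provides the projection matrix and an independent
    recursion simulator, dominant-eigenvalue colony growth rates,
    expected adult worker lifespans, and elasticity analysis of the
    growth rate to age-dependent (senescent) and age-independent
    (extrinsic) worker mortality by numeric perturbation with an
    analytic eigenvector-based cross-check.  Ships three calibrated
    seasonal parameter scenarios (summer, spring/fall, winter), a
    seeded ensemble sampler for robustness checks, a brood-survival
    sweep, and reporting helpers that regenerate the seasonal
    comparison tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
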
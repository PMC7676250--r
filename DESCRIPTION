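Package: nutrisim
Title: Simulating the Nutrition Transition and Long-Term Food Demand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An anthropometric simulator of long-term national food demand.
    From per-capita income and cohort population projections it projects body
    height, body-mass-index (BMI) class distributions, basal metabolic rates
    via the Schofield equations, physical activity levels, per-capita food
    intake, household food waste and a four-group dietary composition on a
    5-year country-timestep grid (1965-2100). Includes regression machinery
    for fitting all model parameters from observation panels (saturating
    income curves and power laws), additive calibration to reported data,
    counterfactual analyses (eliminating underweight, overweight, inactivity
    or waste), a chained decomposition of demand growth into demographic and
    behavioural drivers, k-fold country cross-validation, and a synthetic
    world generator so the whole pipeline can be exercised and validated
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
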
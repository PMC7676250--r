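# ---------------------------------------------------------------------------
# Whole-model fitting from observation panels, and country cross-validation.
# ---------------------------------------------------------------------------

#' Fit the full parameter set from observation panels
#'
#' Estimates every regression parameter of the demand model from
#' observation panels and income/population drivers:
#' \itemize{
#'   \item height power law (`alpha`, `beta` per sex) from young-adult
#'     heights against the trailing-mean diet-quality calories;
#'   \item BMI-share saturation curves per (class, age group, sex);
#'   \item the waste curve (`epsilon`, `zeta`) from the ratio of observed
#'     demand to the model's own intake reconstruction (intake is not
#'     directly observable, so it is computed from the fitted
#'     anthropometric parameters and the drivers);
#'   \item the three diet-tree curves from the observed composition
#'     (animal share of total, empty share of plant, fruit/veg/nut share
#'     of nutritious-plant calories).
#' }
#' Non-regression constants (Schofield coefficients, activity-level
#' parameters, the pregnancy add-on, representative BMIs) are taken from
#' `base_params`.
#'
#' @param drivers An `ns_drivers` object.
#' @param observations An `ns_observations`-style list with panels
#'   `height`, `bmi_shares`, `demand`, `composition`, `diet_quality`.
#' @param base_params Source of the non-fitted constants (default
#'   [default_parameters()]).
#' @return An `ns_params` with the fitted values; individual `ns_fit`
#'   objects in the `fits` attribute.
#' @export
fit_model <- function(drivers, observations, base_params = default_parameters()) {
  fits <- list()

  hfit <- fit_height_regression(observations$height, observations$diet_quality)
  fits$height <- attr(hfit, "fits")

  bfit <- fit_bmi_shares(observations$bmi_shares, drivers$income)
  fits$bmi <- attr(bfit, "fits")

  params <- base_params
  params$height <- tibble::tibble(sex = hfit$sex, alpha = hfit$alpha, beta = hfit$beta)
  params$bmi <- tibble::as_tibble(bfit)

  # intake reconstruction with fitted anthropometrics, observed diet quality
  recon <- run_scenario(drivers, params, g_panel = observations$diet_quality)
  ratio_dat <- dplyr::inner_join(
    observations$demand, recon$energy[, c("country", "year", "intake_kcal")],
    by = c("country", "year")) %>%
    dplyr::inner_join(drivers$income, by = c("country", "year"))
  wfit <- fit_saturating(ratio_dat$income,
                         ratio_dat$demand_kcal / ratio_dat$intake_kcal,
                         offset = 1)
  fits$waste <- wfit
  params$waste <- c(epsilon = wfit$par[["asymptote"]], zeta = wfit$par[["halfsat"]])

  comp <- dplyr::inner_join(observations$composition, drivers$income,
                            by = c("country", "year"))
  plant <- comp$total_kcal - comp$animal_kcal
  nutri <- plant - comp$empty_kcal
  tree <- list(
    animal = fit_saturating(comp$income, comp$animal_kcal / comp$total_kcal,
                            share_constraints = TRUE),
    empty = fit_saturating(comp$income, comp$empty_kcal / plant,
                           share_constraints = TRUE),
    fruitveg = fit_saturating(comp$income, comp$fvn_kcal / nutri,
                              share_constraints = TRUE))
  fits$diet <- tree
  params$diet <- tibble::tibble(
    group = names(tree),
    asymptote = purrr::map_dbl(tree, ~ .x$par[["asymptote"]]),
    halfsat = purrr::map_dbl(tree, ~ .x$par[["halfsat"]]))

  out <- .check_params(params)
  attr(out, "fits") <- fits
  out
}

#' Compare two parameter sets
#'
#' Relative errors of every fitted Greek-letter parameter (height alpha
#' and beta per sex; BMI base/delta/halfsat per stratum; waste epsilon and
#' zeta; diet-tree asymptotes and half-saturations) of `fitted` against
#' `truth`. Used for simulate-and-refit validation.
#'
#' @param fitted,truth `ns_params` objects.
#' @return Tibble `parameter`, `truth`, `fitted`, `rel_error`.
#' @export
compare_params <- function(fitted, truth) {
  rows <- list()
  add <- function(name, tv, fv) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      parameter = name, truth = tv, fitted = fv,
      rel_error = abs(fv - tv) / pmax(abs(tv), 1e-12))
  }
  for (s in sexes()) {
    ht <- truth$height[truth$height$sex == s, ]
    hf <- fitted$height[fitted$height$sex == s, ]
    add(paste0("height_alpha_", s), ht$alpha, hf$alpha)
    add(paste0("height_beta_", s), ht$beta, hf$beta)
  }
  key <- function(p) paste(p$age_group, p$sex, p$bmi_class, sep = "/")
  tb <- truth$bmi; fb <- fitted$bmi[match(key(truth$bmi), key(fitted$bmi)), ]
  for (i in seq_len(nrow(tb))) {
    add(paste0("bmi_base_", key(tb)[i]), tb$base[i], fb$base[i])
    add(paste0("bmi_delta_", key(tb)[i]), tb$delta[i], fb$delta[i])
    add(paste0("bmi_halfsat_", key(tb)[i]), tb$halfsat[i], fb$halfsat[i])
  }
  add("waste_epsilon", truth$waste[["epsilon"]], fitted$waste[["epsilon"]])
  add("waste_zeta", truth$waste[["zeta"]], fitted$waste[["zeta"]])
  for (g in truth$diet$group) {
    td <- truth$diet[truth$diet$group == g, ]
    fd <- fitted$diet[fitted$diet$group == g, ]
    add(paste0("diet_asymptote_", g), td$asymptote, fd$asymptote)
    add(paste0("diet_halfsat_", g), td$halfsat, fd$halfsat)
  }
  dplyr::bind_rows(rows)
}

#' Five-fold (or k-fold) country cross-validation of the model
#'
#' Countries are partitioned into folds by seed; for each fold the full
#' parameter set is fitted on the remaining countries' observations and
#' the held-out countries are predicted at the evaluation year by running
#' the model with the fitted parameters (using the held-out countries'
#' observed diet-quality panel as the height driver, as in fitting).
#' Out-of-sample R-squared is reported per indicator: young-adult
#' `height`, `bmi_shares` (pooled over strata), per-capita `demand` and
#' the four-group `composition` (pooled).
#'
#' @param drivers An `ns_drivers`.
#' @param observations An `ns_observations`-style list.
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param eval_year Evaluation year (default 2010).
#' @param base_params Non-fitted constants for [fit_model()].
#' @return An `ns_cv` report (see [kfold_cv()]).
#' @export
cv_model <- function(drivers, observations, k = 5, seed = 1, eval_year = 2010,
                     base_params = default_parameters()) {
  subset_panels <- function(obj, ctry) {
    out <- lapply(obj, function(p) {
      if (is.data.frame(p) && "country" %in% names(p)) {
        p[p$country %in% ctry, , drop = FALSE]
      } else p
    })
    out
  }
  countries <- sort(unique(drivers$income$country))

  fit_predict <- function(train, test) {
    obs_train <- subset_panels(observations[c("height", "bmi_shares", "demand",
                                              "composition", "diet_quality")], train)
    drv_train <- structure(subset_panels(unclass(drivers)[c("income", "population")],
                                         train), class = "ns_drivers")
    pars <- fit_model(drv_train, obs_train, base_params)
    drv_test <- structure(subset_panels(unclass(drivers)[c("income", "population")],
                                        test), class = "ns_drivers")
    obs_test <- subset_panels(observations[c("height", "bmi_shares", "demand",
                                             "composition", "diet_quality")], test)
    pred <- run_scenario(drv_test, pars, g_panel = obs_test$diet_quality)

    hx <- dplyr::inner_join(
      dplyr::filter(obs_test$height, .data$year == eval_year, .data$age == "15-19"),
      dplyr::filter(pred$height, .data$year == eval_year, .data$age == "15-19"),
      by = c("country", "age", "sex"), suffix = c("_obs", "_hat"))
    sx <- dplyr::inner_join(
      dplyr::filter(obs_test$bmi_shares, .data$year == eval_year),
      dplyr::filter(pred$bmi_shares, .data$year == eval_year),
      by = c("country", "age_group", "sex", "bmi_class"), suffix = c("_obs", "_hat"))
    dx <- dplyr::inner_join(
      dplyr::filter(obs_test$demand, .data$year == eval_year),
      dplyr::filter(pred$energy, .data$year == eval_year),
      by = "country")
    cx <- dplyr::inner_join(
      dplyr::filter(obs_test$composition, .data$year == eval_year),
      dplyr::filter(pred$composition, .data$year == eval_year),
      by = "country", suffix = c("_obs", "_hat"))
    dplyr::bind_rows(
      tibble::tibble(indicator = "height", observed = hx$height_cm_obs,
                     predicted = hx$height_cm_hat),
      tibble::tibble(indicator = "bmi_shares", observed = sx$share_obs,
                     predicted = sx$share_hat),
      tibble::tibble(indicator = "demand", observed = dx$demand_kcal.x,
                     predicted = dx$demand_kcal.y),
      tibble::tibble(indicator = "composition",
                     observed = c(cx$animal_kcal_obs, cx$empty_kcal_obs,
                                  cx$fvn_kcal_obs, cx$staple_kcal_obs),
                     predicted = c(cx$animal_kcal_hat, cx$empty_kcal_hat,
                                   cx$fvn_kcal_hat, cx$staple_kcal_hat)))
  }
  kfold_cv(countries, k, seed, fit_predict)
}
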
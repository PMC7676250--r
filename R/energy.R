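# ---------------------------------------------------------------------------
# Energy: Schofield BMR, physical activity levels, intake aggregation.
# ---------------------------------------------------------------------------

#' Schofield bracket for an age cohort
#'
#' Cohorts map to Schofield brackets by their midpoint age: e.g. `15-19`
#' (midpoint 17.5) falls into the `10-18` bracket, everything from 60
#' upwards into `60+`.
#'
#' @param cohort Character vector of cohort labels, or numeric ages.
#' @return Character vector of bracket labels.
#' @export
schofield_bracket <- function(cohort) {
  age <- if (is.numeric(cohort)) cohort else {
    mid <- cohort_midpoints()[cohort]
    if (anyNA(mid)) stop("unmapped age cohort: ",
                         paste(cohort[is.na(mid)], collapse = ", "))
    unname(mid)
  }
  dplyr::case_when(
    age < 3 ~ "0-3",
    age < 10 ~ "3-10",
    age < 18 ~ "10-18",
    age < 30 ~ "18-30",
    age < 60 ~ "30-60",
    TRUE ~ "60+"
  )
}

#' Basal metabolic rate (Schofield)
#'
#' `BMR = gamma * W + delta` in kcal/day, with the weight-based
#' coefficients of the bracket containing the cohort's midpoint age.
#'
#' @param weight Body weight in kg (> 0; vectorized).
#' @param cohort Age cohort label (or numeric age), recycled against
#'   `weight`.
#' @param sex `"male"` or `"female"`, recycled.
#' @param coeffs Coefficient table; default [schofield_table()].
#' @return BMR in kcal/day.
#' @export
#' @examples
#' bmr(70, "30-34", "male")  # about 1676 kcal/day
bmr <- function(weight, cohort, sex, coeffs = schofield_table()) {
  if (any(weight < 0)) stop("negative body weight")
  br <- schofield_bracket(cohort)
  key <- paste(br, sex)
  lut_g <- stats::setNames(coeffs$gamma_kcal_per_kg, paste(coeffs$bracket, coeffs$sex))
  lut_d <- stats::setNames(coeffs$delta_kcal, paste(coeffs$bracket, coeffs$sex))
  if (anyNA(lut_g[key])) stop("no Schofield coefficients for: ",
                              paste(unique(key[is.na(lut_g[key])]), collapse = ", "))
  unname(lut_g[key] * weight + lut_d[key])
}

#' Inactivity share at a given income
#'
#' Saturating curve `p(Y) = base + delta * Y / (halfsat + Y)` per age
#' group and sex, clipped to `[0, 1]`.
#'
#' @param income Income (>= 0; vectorized).
#' @param age_group,sex Stratum selectors (see [age_groups()]).
#' @param pal_params PAL parameter block (`ns_params$pal` layout).
#' @return Inactivity share in `[0, 1]`.
#' @export
inactivity_share <- function(income, age_group, sex,
                             pal_params = default_parameters()$pal) {
  if (any(income < 0)) stop("negative income")
  cur <- pal_params$curve
  row <- cur[cur$age_group == age_group & cur$sex == sex, ]
  if (nrow(row) != 1) stop("no PAL curve for stratum ", age_group, "/", sex)
  p <- row$base + row$delta * income / (row$halfsat + income)
  pmin(pmax(p, 0), 1)
}

#' Physical activity level multiplier
#'
#' The income-dependent inactivity share `p` is translated into a PAL by
#' mixing the sedentary-lifestyle and active-lifestyle multipliers:
#' `A = p * sedentary + (1 - p) * active`.
#'
#' @inheritParams inactivity_share
#' @return Dimensionless PAL multiplier (within `[1.2, 2.5]` for the
#'   default multipliers).
#' @export
#' @examples
#' pal(0, "0-14", "male")      # children: income-flat
#' pal(50000, "60+", "female") # more sedentary at high income
pal <- function(income, age_group, sex, pal_params = default_parameters()$pal) {
  p <- inactivity_share(income, age_group, sex, pal_params)
  p * pal_params$sedentary + (1 - p) * pal_params$active
}

#' Per-class food intake
#'
#' Elementwise `(gamma * W + delta) * A`: the Schofield BMR of each
#' (BMI class, cohort, sex) body weight times the stratum's activity
#' multiplier.
#'
#' @param weight Body weight in kg.
#' @param pal_multiplier Activity multiplier `A`.
#' @param cohort,sex Cohort and sex (recycled).
#' @param coeffs Schofield coefficient table.
#' @return Intake in kcal/cap/day.
#' @export
intake_per_class <- function(weight, pal_multiplier, cohort, sex,
                             coeffs = schofield_table()) {
  bmr(weight, cohort, sex, coeffs) * pal_multiplier
}

#' Aggregate per-class intake to country level
#'
#' Population- and share-weighted mean of per-class intakes, plus the
#' pregnancy/lactation add-on: a sustained `N` kcal/day for one year per
#' newborn, approximated by `N * P(0-4)/5` (the 5-year birth cohort
#' divided by 5 approximates annual births), expressed per capita.
#'
#' @param intake Tibble `country`, `age`, `sex`, `bmi_class`, `intake_kcal`.
#' @param shares Tibble `country`, `age_group`, `sex`, `bmi_class`, `share`
#'   (normalized within stratum).
#' @param population Tibble `country`, `age`, `sex`, `population`.
#' @param pregnancy_kcal Add-on `N` in kcal/day per newborn-year
#'   (default 460).
#' @return Tibble `country`, `intake_kcal` (kcal/cap/day).
#' @export
aggregate_intake <- function(intake, shares, population, pregnancy_kcal = 460) {
  pop_tot <- population %>%
    dplyr::group_by(.data$country) %>%
    dplyr::summarise(total = sum(.data$population), .groups = "drop")
  if (any(pop_tot$total <= 0)) stop("zero total population")
  dat <- intake %>%
    dplyr::mutate(age_group = cohort_age_group(.data$age)) %>%
    dplyr::inner_join(shares, by = c("country", "age_group", "sex", "bmi_class")) %>%
    dplyr::inner_join(population, by = c("country", "age", "sex"))
  num <- dat %>%
    dplyr::group_by(.data$country) %>%
    dplyr::summarise(num = sum(.data$intake_kcal * .data$share * .data$population),
                     .groups = "drop")
  newborn <- population %>%
    dplyr::filter(.data$age == "0-4") %>%
    dplyr::group_by(.data$country) %>%
    dplyr::summarise(newborn = sum(.data$population), .groups = "drop")
  num %>%
    dplyr::left_join(pop_tot, by = "country") %>%
    dplyr::left_join(newborn, by = "country") %>%
    dplyr::mutate(
      newborn = dplyr::coalesce(.data$newborn, 0),
      intake_kcal = .data$num / .data$total +
        pregnancy_kcal * (.data$newborn / 5) / .data$total
    ) %>%
    dplyr::select("country", "intake_kcal")
}
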
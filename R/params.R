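# ---------------------------------------------------------------------------
# ParameterSet: every fitted or assumed constant of the demand model.
# ---------------------------------------------------------------------------

#' Bundled Schofield basal-metabolic-rate coefficients
#'
#' Weight-based Schofield (1985) coefficients on the brackets
#' 0-3, 3-10, 10-18, 18-30, 30-60, 60+ years by sex, stored in kcal/day
#' (converted from the original MJ/day table at 4.184 kJ/kcal). BMR for a
#' person of weight W kg is `gamma_kcal_per_kg * W + delta_kcal`.
#'
#' @return Tibble with columns `bracket`, `sex`, `gamma_kcal_per_kg`,
#'   `delta_kcal`.
#' @export
schofield_table <- function() {
  path <- system.file("extdata", "schofield_coefficients.csv", package = "nutrisim")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Bundled growth-standard reference table (stylized)
#'
#' Reference median height (cm) and median BMI (kg/m2) by single year of age
#' 0-18 and sex. This is a stylized synthetic stand-in shaped like the WHO
#' child/adolescent growth standards; users can supply the official tables
#' in the same CSV schema via the `standard` arguments of the height
#' functions.
#'
#' @return Tibble with columns `age`, `sex`, `height_cm`, `median_bmi`.
#' @export
growth_standard <- function() {
  path <- system.file("extdata", "growth_standard_synthetic.csv", package = "nutrisim")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

.default_bmi_share_params <- function() {
  # Within each (age group, sex) stratum the classes share one half-saturation
  # income, baselines sum to 1 and saturation deltas sum to 0, so the raw
  # curves already form a proper distribution at every income.
  adult_classes <- bmi_class_table("adult")$bmi_class
  child_classes <- bmi_class_table("child")$bmi_class
  strat <- function(age_group, sex, classes, base, delta, halfsat) {
    stopifnot(abs(sum(base) - 1) < 1e-12, abs(sum(delta)) < 1e-12)
    tibble::tibble(age_group = age_group, sex = sex, bmi_class = classes,
                   base = base, delta = delta, halfsat = halfsat)
  }
  dplyr::bind_rows(
    strat("0-14", "male", child_classes,
          base  = c(0.16, 0.22, 0.52, 0.07, 0.03),
          delta = c(-0.13, -0.15, 0.09, 0.11, 0.08), halfsat = 4500),
    strat("0-14", "female", child_classes,
          base  = c(0.14, 0.21, 0.55, 0.07, 0.03),
          delta = c(-0.11, -0.14, 0.07, 0.11, 0.07), halfsat = 4500),
    strat("15-59", "male", adult_classes,
          base  = c(0.24, 0.24, 0.41, 0.08, 0.02, 0.01),
          delta = c(-0.21, -0.17, -0.12, 0.28, 0.15, 0.07), halfsat = 6000),
    strat("15-59", "female", adult_classes,
          base  = c(0.22, 0.22, 0.42, 0.09, 0.03, 0.02),
          delta = c(-0.19, -0.15, -0.14, 0.24, 0.15, 0.09), halfsat = 5500),
    strat("60+", "male", adult_classes,
          base  = c(0.26, 0.23, 0.39, 0.08, 0.03, 0.01),
          delta = c(-0.23, -0.16, -0.13, 0.27, 0.17, 0.08), halfsat = 6500),
    strat("60+", "female", adult_classes,
          base  = c(0.25, 0.22, 0.38, 0.09, 0.04, 0.02),
          delta = c(-0.22, -0.15, -0.14, 0.24, 0.17, 0.10), halfsat = 6000)
  )
}

.default_pal_params <- function() {
  list(
    sedentary = 1.53,
    active = 1.76,
    # inactivity share p(Y) = base + delta * Y / (halfsat + Y), per age
    # group and sex; children income-flat, inactivity much more common in
    # retirement-age adults.
    curve = dplyr::bind_rows(
      tibble::tibble(age_group = "0-14", sex = sexes(),
                     base = 0.12, delta = 0.00, halfsat = 8000),
      tibble::tibble(age_group = "15-59", sex = sexes(),
                     base = c(0.10, 0.14), delta = c(0.30, 0.32), halfsat = 8000),
      tibble::tibble(age_group = "60+", sex = sexes(),
                     base = c(0.25, 0.28), delta = c(0.35, 0.35), halfsat = 8000)
    )
  )
}

#' Default model parameter set
#'
#' Returns the full parameter set of the demand model: per-sex height
#' power-law coefficients, BMI-share saturation curves per (class, age
#' group, sex), physical-activity parameters, the household-waste curve,
#' the nested diet-tree curves, the pregnancy/lactation add-on and the
#' Schofield coefficient table. These defaults are also the "true"
#' parameters of the synthetic world generator, chosen to produce
#' plausible national panels (e.g. intake near 2000-2300 kcal/cap/day,
#' waste ratios saturating around 1.45, animal-calorie shares saturating
#' near 45%).
#'
#' @return An object of class `ns_params` (a named list).
#' @export
#' @examples
#' p <- default_parameters()
#' p$waste
default_parameters <- function() {
  structure(list(
    height = tibble::tibble(
      sex = sexes(),
      alpha = c(115, 108),   # cm at G = 1 kcal/cap/day
      beta = c(0.060, 0.055) # dimensionless, sub-linear in diet quality
    ),
    bmi = .default_bmi_share_params(),
    pal = .default_pal_params(),
    waste = c(epsilon = 0.45, zeta = 10000),
    diet = tibble::tibble(
      group = c("animal", "empty", "fruitveg"),
      asymptote = c(0.45, 0.35, 0.25),
      halfsat = c(8000, 6000, 4000)
    ),
    pregnancy_kcal = 460,
    schofield = schofield_table(),
    child_bmi_sd_frac = 0.10  # one z-score SD as fraction of median BMI
  ), class = "ns_params")
}

#' @export
print.ns_params <- function(x, ...) {
  cat("<ns_params> food demand model parameter set\n")
  cat("  height: alpha =", paste(signif(x$height$alpha, 5), collapse = "/"),
      " beta =", paste(signif(x$height$beta, 5), collapse = "/"), "(male/female)\n")
  cat("  bmi:   ", nrow(x$bmi), "share curves over",
      length(unique(x$bmi$age_group)), "age groups x 2 sexes\n")
  cat("  pal:    sedentary", x$pal$sedentary, "active", x$pal$active, "\n")
  cat("  waste:  epsilon", signif(x$waste[["epsilon"]], 5),
      "zeta", signif(x$waste[["zeta"]], 6), "\n")
  cat("  diet:   asymptotes",
      paste(signif(x$diet$asymptote, 4), collapse = "/"),
      " half-saturations", paste(signif(x$diet$halfsat, 6), collapse = "/"), "\n")
  cat("  pregnancy add-on:", x$pregnancy_kcal, "kcal/day per newborn-year\n")
  invisible(x)
}

.check_params <- function(params) {
  stopifnot(inherits(params, "ns_params"))
  with(params, {
    stopifnot(all(height$alpha > 0), all(height$beta >= 0), all(height$beta < 1))
    stopifnot(all(bmi$halfsat > 0), all(bmi$base >= 0), all(bmi$base <= 1))
    stopifnot(params$waste[["epsilon"]] >= 0, params$waste[["zeta"]] > 0)
    stopifnot(all(diet$asymptote >= 0), all(diet$asymptote <= 1), all(diet$halfsat > 0))
    stopifnot(pal$sedentary < pal$active, pal$sedentary >= 1.2, pal$active <= 2.5)
    stopifnot(pregnancy_kcal >= 0)
  })
  invisible(params)
}

#' Write / read a parameter set as JSON
#'
#' Serializes every component of an `ns_params` object (tables as
#' data-frame JSON) so fitted parameters can be stored and reloaded by the
#' command-line pipeline.
#'
#' @param params An `ns_params` object.
#' @param path JSON file path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns an `ns_params` object.
#' @export
write_params <- function(params, path) {
  .check_params(params)
  payload <- unclass(params)
  payload$waste <- as.list(params$waste)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    height = tibble::as_tibble(raw$height),
    bmi = tibble::as_tibble(raw$bmi),
    pal = list(sedentary = raw$pal$sedentary, active = raw$pal$active,
               curve = tibble::as_tibble(raw$pal$curve)),
    waste = c(epsilon = raw$waste$epsilon, zeta = raw$waste$zeta),
    diet = tibble::as_tibble(raw$diet),
    pregnancy_kcal = raw$pregnancy_kcal,
    schofield = tibble::as_tibble(raw$schofield),
    child_bmi_sd_frac = raw$child_bmi_sd_frac
  )
  .check_params(structure(out, class = "ns_params"))
}
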
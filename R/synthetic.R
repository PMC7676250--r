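# ---------------------------------------------------------------------------
# Synthetic worlds: drivers and noisy observation panels from known
# parameters, so fitting, calibration, cross-validation and scenarios can
# be exercised end-to-end without external data.
# ---------------------------------------------------------------------------

#' Specify a synthetic world
#'
#' A synthetic world is a set of countries with logistic income growth
#' between country-specific floors and ceilings (spanning roughly
#' 500-60000 USD2005 PPP, wide enough to identify every half-saturation
#' constant), a cohort-component population following a demographic
#' transition (fertility declining with income, mortality advancing
#' cohorts, so pyramids age as countries grow rich), the true model
#' parameter set, and observation noise scales.
#'
#' @param n_countries Number of countries (default 30).
#' @param seed Integer seed; fully determines the world.
#' @param truth True `ns_params` used to generate observations.
#' @param noise Named list of noise scales: `calorie` (log-normal SD on
#'   calorie panels), `share_logit` (Gaussian SD on share logits),
#'   `height` (log-normal SD on heights). Zero gives exact forward-model
#'   observations.
#' @param years Timestep grid (default the full 1965-2100 grid).
#' @return An `ns_world_spec` list.
#' @export
world_spec <- function(n_countries = 30, seed = 1,
                       truth = default_parameters(),
                       noise = list(calorie = 0.02, share_logit = 0.05,
                                    height = 0.005),
                       years = timestep_grid()) {
  stopifnot(n_countries >= 1, all(unlist(noise) >= 0))
  structure(list(n_countries = n_countries, seed = as.integer(seed),
                 truth = truth, noise = noise, years = years),
            class = "ns_world_spec")
}

.fertility <- function(income) {
  # births per woman per 5-year step; declines from ~0.75 (TFR ~5) towards
  # ~0.2 (TFR ~1.4) with income -> demographic transition / ageing
  0.75 - 0.55 * income / (5000 + income)
}

.survival <- function() {
  # 5-year cohort survival via a Gompertz-like mortality curve
  mid <- cohort_midpoints()
  m <- 0.0005 + 1.2e-5 * exp(0.082 * mid)
  exp(-5 * m)
}

#' Generate synthetic driver panels
#'
#' Income follows a logistic path between a country-specific floor and
#' ceiling; population evolves by a simple cohort-component rule (births
#' from a fertility proxy that declines with income, survival advancing
#' cohorts one class per step, the 100+ class absorbing). The same seed
#' always yields identical panels.
#'
#' @param spec An `ns_world_spec`.
#' @return An `ns_drivers` list with `income` and `population` panels.
#' @export
make_drivers <- function(spec) {
  stopifnot(inherits(spec, "ns_world_spec"))
  n <- spec$n_countries
  years <- spec$years
  countries <- sprintf("S%02d", seq_len(n))
  cohorts <- age_cohorts()
  nc <- length(cohorts)
  surv <- .survival()

  pars <- withr::with_seed(spec$seed, {
    tibble::tibble(
      country = countries,
      floor = exp(stats::runif(n, log(400), log(3000))),
      ceiling = exp(stats::runif(n, log(20000), log(80000))),
      rate = stats::runif(n, 0.03, 0.09),
      midyear = stats::runif(n, 1975, 2060),
      pop0 = exp(stats::runif(n, log(2e6), log(2e8)))
    )
  })

  Y <- outer(seq_len(n), seq_along(years), function(i, j) {
    pars$floor[i] + (pars$ceiling[i] - pars$floor[i]) *
      stats::plogis(pars$rate[i] * (years[j] - pars$midyear[i]))
  })

  # initial young pyramid, then cohort-component stepping
  w0 <- exp(-0.035 * cohort_midpoints())
  w0 <- w0 / sum(w0)
  fertile <- which(cohort_midpoints() >= 15 & cohort_midpoints() < 50)
  P <- array(0, c(nc, 2, n, length(years)))
  for (i in seq_len(n)) for (s in 1:2) P[, s, i, 1] <- pars$pop0[i] * w0 / 2
  for (k in seq_along(years)[-1]) {
    for (i in seq_len(n)) {
      prev <- P[, , i, k - 1]
      cur <- matrix(0, nc, 2)
      cur[2:nc, ] <- prev[1:(nc - 1), ] * surv[1:(nc - 1)]
      cur[nc, ] <- cur[nc, ] + prev[nc, ] * surv[nc]
      births <- .fertility(Y[i, k - 1]) * sum(prev[fertile, 2])
      cur[1, 1] <- births * 0.512
      cur[1, 2] <- births * 0.488
      P[, , i, k] <- cur
    }
  }

  income <- tibble::tibble(
    country = rep(countries, times = length(years)),
    year = rep(years, each = n),
    income = as.vector(Y))
  population <- tibble::tibble(
    country = rep(rep(countries, each = nc * 2), times = length(years)),
    year = rep(years, each = nc * 2 * n),
    age = rep(cohorts, times = 2 * n * length(years)),
    sex = rep(rep(sexes(), each = nc), times = n * length(years)),
    population = as.vector(P))
  structure(list(income = income, population = population, spec = pars),
            class = "ns_drivers")
}

#' @export
print.ns_drivers <- function(x, ...) {
  cat("<ns_drivers>", length(unique(x$income$country)), "countries,",
      length(unique(x$income$year)), "timesteps, income range",
      paste(signif(range(x$income$income), 3), collapse = " - "), "\n")
  invisible(x)
}

.logit_perturb <- function(share, sd) {
  if (sd == 0) return(share)
  z <- stats::qlogis(pmin(pmax(share, 1e-12), 1 - 1e-12))
  stats::plogis(z + stats::rnorm(length(z), 0, sd))
}

#' Generate synthetic observation panels
#'
#' Runs the forward model with the true parameters and perturbs its
#' outputs with seeded noise: multiplicative log-normal noise on calorie
#' quantities and heights, additive Gaussian noise on the logits of BMI
#' shares (renormalized afterwards). With zero noise the observations
#' equal the forward-model output exactly. The observed demand panel is
#' the sum of the perturbed composition groups, keeping the panels
#' internally consistent.
#'
#' @param drivers An `ns_drivers` object.
#' @param truth True `ns_params`.
#' @param noise Noise scales (see [world_spec()]).
#' @param seed Integer seed for the noise draws.
#' @return An `ns_observations` list with panels `height`, `bmi_shares`,
#'   `demand`, `composition`, `diet_quality`, and the uncalibrated truth
#'   run in attribute `baseline`.
#' @export
make_observations <- function(drivers, truth = default_parameters(),
                              noise = list(calorie = 0, share_logit = 0, height = 0),
                              seed = 1) {
  base <- run_scenario(drivers, truth)
  noise <- utils::modifyList(list(calorie = 0, share_logit = 0, height = 0), noise)

  obs <- withr::with_seed(seed, {
    height <- base$height %>%
      dplyr::filter(.data$age == "15-19") %>%
      dplyr::mutate(height_cm = .data$height_cm *
                      exp(stats::rnorm(dplyr::n(), 0, noise$height)))

    shares <- if (noise$share_logit == 0) base$bmi_shares else {
      base$bmi_shares %>%
        dplyr::mutate(share = .logit_perturb(.data$share, noise$share_logit)) %>%
        dplyr::group_by(.data$country, .data$year, .data$age_group, .data$sex) %>%
        dplyr::mutate(share = .data$share / sum(.data$share)) %>%
        dplyr::ungroup()
    }

    comp <- if (noise$calorie == 0) base$composition else {
      base$composition %>%
        dplyr::mutate(
          animal_kcal = .data$animal_kcal * exp(stats::rnorm(dplyr::n(), 0, noise$calorie)),
          empty_kcal = .data$empty_kcal * exp(stats::rnorm(dplyr::n(), 0, noise$calorie)),
          fvn_kcal = .data$fvn_kcal * exp(stats::rnorm(dplyr::n(), 0, noise$calorie)),
          staple_kcal = .data$staple_kcal * exp(stats::rnorm(dplyr::n(), 0, noise$calorie)),
          total_kcal = .data$animal_kcal + .data$empty_kcal +
            .data$fvn_kcal + .data$staple_kcal)
    }

    demand <- comp %>% dplyr::select("country", "year", demand_kcal = "total_kcal")
    dq <- comp %>%
      dplyr::mutate(g_kcal = .data$animal_kcal + .data$empty_kcal) %>%
      dplyr::select("country", "year", "g_kcal")
    list(height = height, bmi_shares = shares, demand = demand,
         composition = comp, diet_quality = dq)
  })

  for (kind in c("height", "bmi_shares", "demand", "composition", "diet_quality")) {
    v <- validate_panel(obs[[kind]], kind)
    if (nrow(v)) {
      stop("noise broke the ", kind, " panel invariants: ",
           paste(v$rule, v$detail, sep = ": ", collapse = "; "))
    }
  }
  structure(obs, class = "ns_observations", baseline = base)
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: drivers plus observations from the spec's truth
#' and noise settings.
#'
#' @param spec An `ns_world_spec`.
#' @return List with `drivers`, `observations`, `truth` and the `spec`.
#' @export
make_world <- function(spec = world_spec()) {
  drivers <- make_drivers(spec)
  observations <- make_observations(drivers, spec$truth, spec$noise,
                                    seed = spec$seed + 1L)
  list(drivers = drivers, observations = observations, truth = spec$truth,
       spec = spec)
}
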
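# ---------------------------------------------------------------------------
# Anthropometry: height projection, BMI-class shares, body weight.
# ---------------------------------------------------------------------------

.std_lookup <- function(standard, sex_, ages) {
  ref <- standard[standard$sex == sex_, ]
  stats::approx(ref$age, ref$height_cm, xout = pmin(ages, max(ref$age)),
                rule = 2)$y
}

.std_bmi_lookup <- function(standard, sex_, ages) {
  ref <- standard[standard$sex == sex_, ]
  stats::approx(ref$age, ref$median_bmi, xout = pmin(ages, max(ref$age)),
                rule = 2)$y
}

#' Trailing-mean diet-quality driver
#'
#' The height regression pairs each young-adult height observation at year
#' `t` with the arithmetic mean of the diet-quality calories `G` over the
#' three preceding 5-year timesteps (`t-15`, `t-10`, `t-5`), covering
#' roughly the growing period. When fewer preceding timesteps exist the
#' mean is taken over the available ones, and at the panel start the
#' current-year value is used (fallback, flagged in the `n_lags` column
#' with 0).
#'
#' @param g_panel Diet-quality panel (`country`, `year`, `g_kcal`).
#' @param require_full Keep only years with all three lags? Default FALSE.
#' @return Tibble `country`, `year`, `g_mean`, `n_lags`.
#' @export
trailing_g <- function(g_panel, require_full = FALSE) {
  out <- g_panel %>%
    dplyr::group_by(.data$country) %>%
    dplyr::arrange(.data$year, .by_group = TRUE) %>%
    dplyr::mutate(
      l1 = dplyr::lag(.data$g_kcal, 1),
      l2 = dplyr::lag(.data$g_kcal, 2),
      l3 = dplyr::lag(.data$g_kcal, 3),
      n_lags = (!is.na(.data$l1)) + (!is.na(.data$l2)) + (!is.na(.data$l3)),
      g_mean = dplyr::case_when(
        .data$n_lags == 0 ~ .data$g_kcal,
        TRUE ~ purrr::pmap_dbl(list(.data$l1, .data$l2, .data$l3),
                               function(a, b, c) mean(c(a, b, c), na.rm = TRUE))
      )
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select("country", "year", "g_mean", "n_lags")
  if (require_full) out <- dplyr::filter(out, .data$n_lags == 3)
  out
}

#' Fit the young-adult height regression
#'
#' Regresses observed 15-19 cohort height on the trailing-mean
#' diet-quality calories `G` as the power law `H = alpha * G^beta`,
#' separately by sex, via ordinary least squares in log-log space. Only
#' observations with a full three-lag `G` history are used.
#'
#' @param heights Height panel with rows for the `15-19` cohort
#'   (`country`, `year`, `age`, `sex`, `height_cm`).
#' @param g_panel Diet-quality panel (`country`, `year`, `g_kcal`).
#' @return Tibble `sex`, `alpha`, `beta` with the per-sex fits in the
#'   `fits` attribute.
#' @export
fit_height_regression <- function(heights, g_panel) {
  h <- dplyr::filter(heights, .data$age == "15-19")
  g <- trailing_g(g_panel, require_full = TRUE)
  dat <- dplyr::inner_join(h, g, by = c("country", "year"))
  if (!nrow(dat)) stop("no height observations with a full 3-lag diet-quality history")
  if (any(dat$height_cm <= 0) || any(dat$g_mean <= 0)) {
    stop("height regression requires positive heights and diet-quality values")
  }
  fits <- lapply(sexes(), function(s) {
    d <- dat[dat$sex == s, ]
    if (nrow(d) < 3) stop("need >= 3 observations for sex ", s)
    fit_power_law(d$g_mean, d$height_cm)
  })
  names(fits) <- sexes()
  out <- tibble::tibble(
    sex = sexes(),
    alpha = unname(purrr::map_dbl(fits, ~ .x$par[["alpha"]])),
    beta = unname(purrr::map_dbl(fits, ~ .x$par[["beta"]]))
  )
  attr(out, "fits") <- fits
  out
}

#' Body weight from representative BMI and height
#'
#' `W = B * (H/100)^2` with height in cm converted to metres before
#' squaring.
#'
#' @param bmi Representative BMI (kg/m2).
#' @param height_cm Height in cm.
#' @return Weight in kg (vectorized, recycling as usual).
#' @export
#' @examples
#' body_weight(22.5, 160)  # 57.6 kg
body_weight <- function(bmi, height_cm) {
  if (any(bmi < 0) || any(height_cm < 0)) stop("negative BMI or height")
  bmi * (height_cm / 100)^2
}

#' Advance the height state by one 5-year timestep
#'
#' The new 15-19 cohort height is `alpha * G^beta` per sex; adult cohorts
#' age forward keeping their height (the open 100+ cohort absorbs the
#' incoming 95-99 height); child cohort heights are the growth-standard
#' heights at the cohort midpoint age scaled by the factor by which the
#' 15-19 cohort diverges from the standard's 18-year height. At the first
#' timestep (no `previous` state) all adult cohorts take the new 15-19
#' value for their sex.
#'
#' @param height_params Tibble `sex`, `alpha`, `beta`.
#' @param g Named numeric vector (or single value) of trailing-mean
#'   diet-quality calories per country.
#' @param previous Height panel at the previous timestep, or NULL.
#' @param standard Growth-standard table; default [growth_standard()].
#' @param year Year label attached to the output.
#' @return Height panel tibble for `year` covering all cohorts and sexes.
#' @export
project_height <- function(height_params, g, previous = NULL,
                           standard = growth_standard(), year = NA_integer_) {
  countries <- names(g)
  if (is.null(countries)) countries <- paste0("C", seq_along(g))
  if (any(g < 0)) stop("negative diet-quality driver")
  cohorts <- age_cohorts()
  mid <- cohort_midpoints()
  out <- purrr::map(sexes(), function(s) {
    hp <- height_params[height_params$sex == s, ]
    h15 <- hp$alpha * g^hp$beta
    std18 <- .std_lookup(standard, s, 18)
    H <- matrix(NA_real_, nrow = length(cohorts), ncol = length(g),
                dimnames = list(cohorts, countries))
    child_idx <- which(mid < 15)
    for (a in child_idx) {
      H[a, ] <- .std_lookup(standard, s, mid[[a]]) * h15 / std18
    }
    H["15-19", ] <- h15
    adult_idx <- which(mid >= 20)
    if (is.null(previous)) {
      for (a in adult_idx) H[a, ] <- h15
    } else {
      prev <- previous[previous$sex == s, ]
      pm <- matrix(NA_real_, nrow = length(cohorts), ncol = length(g),
                   dimnames = list(cohorts, countries))
      pm[cbind(prev$age, prev$country)] <- prev$height_cm
      for (a in adult_idx) H[a, ] <- pm[a - 1L, ]
    }
    tibble::tibble(
      country = rep(countries, each = length(cohorts)),
      year = year,
      age = rep(cohorts, times = length(g)),
      sex = s,
      height_cm = as.vector(H)
    )
  })
  dplyr::bind_rows(out)
}

#' Fit BMI-class share curves against income
#'
#' For each (BMI class, age group, sex) stratum independently, fits the
#' saturating share curve `s(Y) = base + delta * Y / (halfsat + Y)` by
#' nonlinear least squares (`delta` may be negative for classes that
#' shrink with income).
#'
#' @param shares BMI-share panel (`country`, `year`, `age_group`, `sex`,
#'   `bmi_class`, `share`).
#' @param income Income panel (`country`, `year`, `income`).
#' @return Tibble `age_group`, `sex`, `bmi_class`, `base`, `delta`,
#'   `halfsat` (the `ns_params$bmi` layout), with per-stratum `ns_fit`
#'   objects in the `fits` attribute.
#' @export
fit_bmi_shares <- function(shares, income) {
  dat <- dplyr::inner_join(shares, income, by = c("country", "year"))
  if (!nrow(dat)) stop("no overlap between share and income panels")
  strata <- dplyr::distinct(dat, .data$age_group, .data$sex, .data$bmi_class)
  fits <- vector("list", nrow(strata))
  rows <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    d <- dat[dat$age_group == st$age_group & dat$sex == st$sex &
               dat$bmi_class == st$bmi_class, ]
    if (length(unique(d$income)) < 4) {
      stop("need >= 4 income levels for stratum ",
           paste(st$age_group, st$sex, st$bmi_class, sep = "/"))
    }
    f <- tryCatch(
      fit_saturating(d$income, d$share, baseline = TRUE, share_constraints = TRUE),
      error = function(e) {
        stop("BMI share fit failed for stratum ",
             paste(st$age_group, st$sex, st$bmi_class, sep = "/"), ": ",
             conditionMessage(e))
      })
    fits[[i]] <- f
    rows[[i]] <- tibble::tibble(
      age_group = st$age_group, sex = st$sex, bmi_class = st$bmi_class,
      base = f$par[["base"]], delta = f$par[["asymptote"]],
      halfsat = f$par[["halfsat"]]
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}

#' Predict BMI-class shares at a given income
#'
#' Evaluates every class curve of a stratum at income `Y`, clips the raw
#' shares to `[0, 1]` and renormalizes so they sum to one.
#'
#' @param bmi_params BMI-share parameter tibble (`ns_params$bmi` layout).
#' @param income Scalar or vector of incomes (>= 0).
#' @param age_group,sex Stratum selectors.
#' @return Tibble `bmi_class` x `income` with columns `income`,
#'   `bmi_class`, `share`.
#' @export
#' @examples
#' p <- default_parameters()
#' predict_bmi_shares(p$bmi, 10000, "15-59", "male")
predict_bmi_shares <- function(bmi_params, income, age_group, sex) {
  if (any(income < 0)) stop("negative income")
  cur <- bmi_params[bmi_params$age_group == age_group & bmi_params$sex == sex, ]
  if (!nrow(cur)) stop("no BMI share parameters for stratum ", age_group, "/", sex)
  raw <- outer(seq_len(nrow(cur)), seq_along(income),
               function(i, j) {
                 hs <- cur$halfsat[i]
                 sat <- ifelse(is.na(hs), 0, income[j] / (hs + income[j]))
                 cur$base[i] + cur$delta[i] * sat
               })
  raw <- pmin(pmax(raw, 0), 1)
  tot <- colSums(raw)
  if (any(tot <= 0)) stop("all raw shares zero; cannot normalize")
  sh <- sweep(raw, 2, tot, "/")
  inc_col <- rep(income, each = nrow(cur))
  cls_col <- rep(cur$bmi_class, times = length(income))
  tibble::tibble(income = inc_col, bmi_class = cls_col, share = as.vector(sh))
}
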
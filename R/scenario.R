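# ---------------------------------------------------------------------------
# Scenario engine: run, calibrate, counterfactuals, growth decomposition,
# global aggregation, prevalence summaries.
# ---------------------------------------------------------------------------

#' Run a food-demand scenario
#'
#' Executes the full model chain for every 5-year timestep in order:
#' diet-quality driver -> young-adult height -> cohort heights -> body
#' weight per BMI class -> activity levels -> per-class intake -> BMI
#' shares -> aggregate intake -> waste/demand -> dietary composition.
#' The run is deterministic: identical inputs give bit-identical results.
#'
#' The diet-quality driver `G` is the trailing mean of animal-source plus
#' empty calories over the three preceding timesteps. By default it is
#' taken from the model's own lagged composition (at the first timestep it
#' is resolved by fixed-point iteration within the step and flagged in the
#' run log); alternatively an observed panel can be supplied via
#' `g_panel`, in which case the first timestep uses that panel's
#' current-year value.
#'
#' @param drivers An `ns_drivers` object (or list with `income` and
#'   `population` panels) covering a consecutive 5-year grid.
#' @param params An `ns_params` parameter set.
#' @param calibration Optional `ns_calibration` factors applied to the
#'   outputs (see [calibrate()]).
#' @param g_panel Optional diet-quality panel (`country`, `year`,
#'   `g_kcal`) overriding the endogenous driver.
#' @param years Optional subset of timesteps (consecutive, on-grid).
#' @param standard Growth-standard table.
#' @return An `ns_scenario` object: tibbles `height`, `bmi_shares`, `pal`,
#'   `energy`, `composition`, `diet_quality`, plus the drivers, parameters,
#'   run `log` and `clip_log`.
#' @export
run_scenario <- function(drivers, params = default_parameters(),
                         calibration = NULL, g_panel = NULL, years = NULL,
                         standard = growth_standard()) {
  prep <- .engine_prep(params, standard)
  avail <- sort(intersect(unique(drivers$income$year), timestep_grid()))
  if (is.null(years)) years <- avail
  years <- sort(unique(as.integer(years)))
  if (!all(years %in% timestep_grid())) stop("years must lie on the 5-year grid")
  if (length(years) > 1 && any(diff(years) != 5)) stop("years must be consecutive 5-year steps")
  dm <- .drivers_matrices(
    list(income = dplyr::filter(drivers$income, .data$year %in% years),
         population = dplyr::filter(drivers$population, .data$year %in% years)),
    years)
  countries <- dm$countries
  C <- length(countries); TT <- length(years)
  nc <- length(prep$cohorts)
  run_log <- character()

  gx <- NULL
  if (!is.null(g_panel)) {
    gx <- matrix(NA_real_, C, TT, dimnames = list(countries, years))
    gp <- dplyr::filter(g_panel, .data$year %in% years)
    gx[cbind(match(gp$country, countries), match(gp$year, years))] <- gp$g_kcal
    if (anyNA(gx)) stop("g_panel does not cover the run grid")
  }

  H_all <- array(NA_real_, c(nc, 2, C, TT))
  S_all <- lapply(prep$nb_of, function(nb) array(NA_real_, c(nb, 2, C, TT)))
  p_all <- A_all <- array(NA_real_, c(3, 2, C, TT))
  I_m <- D_m <- X_m <- ratio_m <- matrix(NA_real_, C, TT)
  L_m <- E_m <- V_m <- R_m <- g_m <- G_m <- matrix(NA_real_, C, TT)

  H_prev <- NULL
  for (k in seq_len(TT)) {
    Yk <- dm$Y[, k]
    Pk <- array(dm$P[, , , k], c(nc, 2, C))
    if (!is.null(gx)) {
      G <- if (k == 1) gx[, 1] else rowMeans(gx[, max(1, k - 3):(k - 1), drop = FALSE])
      if (k == 1) run_log <- c(run_log, paste0(
        "G fallback at ", years[1], ": no lagged history, current-year panel value used"))
      h15 <- rbind(prep$alpha[["male"]] * G^prep$beta[["male"]],
                   prep$alpha[["female"]] * G^prep$beta[["female"]])
      H <- .engine_height(prep, h15, H_prev)
      out <- .engine_year(prep, Yk, Pk, H)
    } else if (k == 1) {
      G <- rep(1000, C)
      for (it in 1:100) {
        h15 <- rbind(prep$alpha[["male"]] * G^prep$beta[["male"]],
                     prep$alpha[["female"]] * G^prep$beta[["female"]])
        H <- .engine_height(prep, h15, NULL)
        out <- .engine_year(prep, Yk, Pk, H)
        if (max(abs(out$g - G) / pmax(abs(out$g), 1)) < 1e-13) break
        G <- out$g
      }
      run_log <- c(run_log, paste0(
        "G fallback at ", years[1],
        ": no lagged history, fixed-point iteration (", it, " iterations)"))
    } else {
      G <- rowMeans(g_m[, max(1, k - 3):(k - 1), drop = FALSE])
      if (k <= 3) run_log <- c(run_log, paste0(
        "G fallback at ", years[k], ": only ", k - 1, " lagged timestep(s) available"))
      h15 <- rbind(prep$alpha[["male"]] * G^prep$beta[["male"]],
                   prep$alpha[["female"]] * G^prep$beta[["female"]])
      H <- .engine_height(prep, h15, H_prev)
      out <- .engine_year(prep, Yk, Pk, H)
    }
    H_all[, , , k] <- H
    for (g in 1:3) S_all[[g]][, , , k] <- out$S[[g]]
    p_all[, , , k] <- out$p; A_all[, , , k] <- out$A
    I_m[, k] <- out$I; D_m[, k] <- out$D; X_m[, k] <- out$X; ratio_m[, k] <- out$ratio
    L_m[, k] <- out$L; E_m[, k] <- out$E; V_m[, k] <- out$V; R_m[, k] <- out$R
    g_m[, k] <- out$g; G_m[, k] <- G
    H_prev <- H
  }

  state <- list(years = years, countries = countries, cohorts = prep$cohorts,
                class_of = prep$class_of, H = H_all, S = S_all, p = p_all,
                A = A_all, I = I_m, D = D_m, X = X_m, ratio = ratio_m,
                L = L_m, E = E_m, V = V_m, R = R_m, g = g_m, G = G_m,
                P = dm$P, Y = dm$Y)
  result <- structure(
    list(state = state, drivers = drivers, params = params,
         standard = standard, calibration = NULL,
         log = run_log,
         clip_log = tibble::tibble(variable = character(), country = character(),
                                   year = integer(), detail = character())),
    class = "ns_scenario")
  result <- .state_tibbles(result)
  if (!is.null(calibration)) result <- apply_calibration(result, calibration)
  result
}

.state_tibbles <- function(result) {
  st <- result$state
  C <- length(st$countries); TT <- length(st$years); nc <- length(st$cohorts)
  idx4 <- function(n1, labs1) tibble::tibble(
    country = rep(rep(st$countries, each = n1 * 2), times = TT),
    year = rep(st$years, each = n1 * 2 * C),
    lab = rep(labs1, times = 2 * C * TT),
    sex = rep(rep(sexes(), each = n1), times = C * TT)
  )
  h <- idx4(nc, st$cohorts) %>%
    dplyr::mutate(height_cm = as.vector(st$H)) %>%
    dplyr::rename(age = "lab") %>%
    dplyr::select("country", "year", "age", "sex", "height_cm")
  shares <- purrr::map2(st$S, seq_along(st$S), function(arr, g) {
    labs <- st$class_of[[g]]
    idx4(length(labs), labs) %>%
      dplyr::mutate(share = as.vector(arr), age_group = age_groups()[g]) %>%
      dplyr::rename(bmi_class = "lab") %>%
      dplyr::select("country", "year", "age_group", "sex", "bmi_class", "share")
  }) %>% dplyr::bind_rows() %>%
    dplyr::arrange(.data$country, .data$year, .data$age_group, .data$sex)
  palt <- idx4(3, age_groups()) %>%
    dplyr::mutate(inactive_share = as.vector(st$p), pal = as.vector(st$A)) %>%
    dplyr::rename(age_group = "lab") %>%
    dplyr::select("country", "year", "age_group", "sex", "inactive_share", "pal")
  cy <- tibble::tibble(country = rep(st$countries, times = TT),
                       year = rep(st$years, each = C))
  energy <- cy %>% dplyr::mutate(
    intake_kcal = as.vector(st$I), demand_kcal = as.vector(st$D),
    waste_kcal = as.vector(st$X), waste_ratio = as.vector(st$ratio))
  comp <- cy %>% dplyr::mutate(
    animal_kcal = as.vector(st$L), empty_kcal = as.vector(st$E),
    fvn_kcal = as.vector(st$V), staple_kcal = as.vector(st$R),
    total_kcal = as.vector(st$D))
  dq <- cy %>% dplyr::mutate(g_kcal = as.vector(st$g))
  result$height <- h
  result$bmi_shares <- shares
  result$pal <- palt
  result$energy <- energy
  result$composition <- comp
  result$diet_quality <- dq
  result
}

#' @export
print.ns_scenario <- function(x, ...) {
  st <- x$state
  cat("<ns_scenario>", length(st$countries), "countries x", length(st$years),
      "timesteps (", min(st$years), "-", max(st$years), ")",
      if (!is.null(x$calibration)) "[calibrated]" else "", "\n")
  glo <- global_aggregate(x)
  show <- glo[glo$year %in% range(glo$year), c("year", "demand_EJ", "intake_EJ", "animal_EJ")]
  print(as.data.frame(show), row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Additive calibration
# ---------------------------------------------------------------------------

#' Derive additive calibration factors at a calibration year
#'
#' For each calibrated variable present in `reported`, the factor is
#' `reported - modeled` at the calibration year: height offsets per
#' (country, cohort, sex), BMI-share offsets per (country, age group, sex,
#' class), per-capita demand offsets per country, and composition share
#' offsets (of total demand) per country. Variables with no reported data
#' get no factor (equivalent to 0) and are noted.
#'
#' @param modeled An `ns_scenario`.
#' @param reported A list of observation panels (any of `height`,
#'   `bmi_shares`, `demand`, `composition`), e.g. an `ns_observations`.
#' @param year Calibration year (must be in the modeled result).
#' @return An `ns_calibration` object.
#' @export
calibrate <- function(modeled, reported, year) {
  stopifnot(inherits(modeled, "ns_scenario"))
  if (!year %in% modeled$state$years) stop("calibration year ", year, " not in the scenario")
  notes <- character()
  cal <- list(year = year)

  if (!is.null(reported$height)) {
    r <- dplyr::filter(reported$height, .data$year == !!year)
    m <- dplyr::filter(modeled$height, .data$year == !!year)
    cal$height <- dplyr::inner_join(
      r, m, by = c("country", "age", "sex"), suffix = c("_rep", "_mod")) %>%
      dplyr::mutate(offset = .data$height_cm_rep - .data$height_cm_mod) %>%
      dplyr::select("country", "age", "sex", "offset")
  } else notes <- c(notes, "height: no reported data, factor 0")

  if (!is.null(reported$bmi_shares)) {
    r <- dplyr::filter(reported$bmi_shares, .data$year == !!year)
    m <- dplyr::filter(modeled$bmi_shares, .data$year == !!year)
    cal$bmi_shares <- dplyr::inner_join(
      r, m, by = c("country", "age_group", "sex", "bmi_class"),
      suffix = c("_rep", "_mod")) %>%
      dplyr::mutate(offset = .data$share_rep - .data$share_mod) %>%
      dplyr::select("country", "age_group", "sex", "bmi_class", "offset")
  } else notes <- c(notes, "bmi_shares: no reported data, factor 0")

  if (!is.null(reported$demand)) {
    r <- dplyr::filter(reported$demand, .data$year == !!year)
    m <- dplyr::filter(modeled$energy, .data$year == !!year)
    cal$demand <- dplyr::inner_join(r, m, by = "country") %>%
      dplyr::mutate(offset = .data$demand_kcal.x - .data$demand_kcal.y) %>%
      dplyr::select("country", "offset")
  } else notes <- c(notes, "demand: no reported data, factor 0")

  if (!is.null(reported$composition)) {
    r <- dplyr::filter(reported$composition, .data$year == !!year)
    m <- dplyr::filter(modeled$composition, .data$year == !!year)
    cal$composition <- dplyr::inner_join(
      r, m, by = "country", suffix = c("_rep", "_mod")) %>%
      dplyr::mutate(
        off_animal = .data$animal_kcal_rep / .data$total_kcal_rep -
          .data$animal_kcal_mod / .data$total_kcal_mod,
        off_empty = .data$empty_kcal_rep / .data$total_kcal_rep -
          .data$empty_kcal_mod / .data$total_kcal_mod,
        off_fvn = .data$fvn_kcal_rep / .data$total_kcal_rep -
          .data$fvn_kcal_mod / .data$total_kcal_mod) %>%
      dplyr::select("country", "off_animal", "off_empty", "off_fvn")
  } else notes <- c(notes, "composition: no reported data, factor 0")

  structure(cal, class = "ns_calibration", notes = notes)
}

#' Apply calibration factors to a scenario
#'
#' Adds the factors to every timestep of the result. Calibrated values are
#' cut off below zero; shares are cut off above one and renormalized;
#' calibrated demand is floored at intake (waste cannot be negative).
#' Every cut is recorded in the `clip_log`.
#'
#' @param result An `ns_scenario`.
#' @param calib An `ns_calibration`.
#' @return The calibrated `ns_scenario`.
#' @export
apply_calibration <- function(result, calib) {
  stopifnot(inherits(result, "ns_scenario"), inherits(calib, "ns_calibration"))
  st <- result$state
  C <- length(st$countries); TT <- length(st$years)
  clips <- list()
  clip <- function(variable, country, year, detail) {
    clips[[length(clips) + 1]] <<- tibble::tibble(
      variable = variable, country = country, year = as.integer(year), detail = detail)
  }

  if (!is.null(calib$height)) {
    hh <- calib$height
    ai <- match(hh$age, st$cohorts); si <- match(hh$sex, sexes())
    ci <- match(hh$country, st$countries)
    keep <- !is.na(ai) & !is.na(si) & !is.na(ci)
    for (r in which(keep)) {
      v <- st$H[ai[r], si[r], ci[r], ] + hh$offset[r]
      neg <- v < 0
      if (any(neg)) {
        v[neg] <- 0
        clip("height", hh$country[r], st$years[neg][1], "height cut off at 0")
      }
      st$H[ai[r], si[r], ci[r], ] <- v
    }
  }

  if (!is.null(calib$bmi_shares)) {
    bb <- calib$bmi_shares
    for (g in 1:3) {
      cur <- bb[bb$age_group == age_groups()[g], ]
      if (!nrow(cur)) next
      off <- array(0, dim(st$S[[g]])[1:3])
      bi <- match(cur$bmi_class, st$class_of[[g]])
      si <- match(cur$sex, sexes()); ci <- match(cur$country, st$countries)
      keep <- !is.na(bi) & !is.na(si) & !is.na(ci)
      off[cbind(bi[keep], si[keep], ci[keep])] <- cur$offset[keep]
      arr <- st$S[[g]] + array(off, dim(st$S[[g]]))  # offsets constant over t
      low <- arr < 0; high <- arr > 1
      if (any(low) || any(high)) {
        n_cut <- sum(low) + sum(high)
        arr[low] <- 0; arr[high] <- 1
        clip("bmi_shares", "(multiple)", st$years[1],
             paste0(n_cut, " share cell(s) cut to [0,1] in age group ", age_groups()[g]))
      }
      tot <- apply(arr, c(2, 3, 4), sum)
      for (s in 1:2) arr[, s, , ] <- arr[, s, , ] / rep(tot[s, , ], each = dim(arr)[1])
      st$S[[g]] <- arr
    }
  }

  # composition shares of the *uncalibrated* demand, before demand moves
  shL <- st$L / st$D; shE <- st$E / st$D; shV <- st$V / st$D

  if (!is.null(calib$demand)) {
    dd <- calib$demand
    ci <- match(dd$country, st$countries)
    keep <- !is.na(ci)
    offv <- numeric(C); offv[ci[keep]] <- dd$offset[keep]
    Dn <- st$D + offv
    floor_hit <- Dn < st$I
    if (any(floor_hit)) {
      idx <- which(floor_hit, arr.ind = TRUE)
      for (r in seq_len(min(nrow(idx), 50))) {
        clip("demand", st$countries[idx[r, 1]], st$years[idx[r, 2]],
             "calibrated demand cut off at intake (zero waste)")
      }
      Dn[floor_hit] <- st$I[floor_hit]
    }
    st$D <- Dn
    st$X <- st$D - st$I
    st$ratio <- st$D / st$I
  }

  if (!is.null(calib$composition)) {
    cc <- calib$composition
    ci <- match(cc$country, st$countries)
    keep <- !is.na(ci)
    oL <- oE <- oV <- numeric(C)
    oL[ci[keep]] <- cc$off_animal[keep]
    oE[ci[keep]] <- cc$off_empty[keep]
    oV[ci[keep]] <- cc$off_fvn[keep]
    shL <- shL + oL; shE <- shE + oE; shV <- shV + oV
  }
  sh_cut <- sum(shL < 0 | shL > 1) + sum(shE < 0 | shE > 1) + sum(shV < 0 | shV > 1)
  if (sh_cut > 0) {
    clip("composition", "(multiple)", st$years[1],
         paste0(sh_cut, " composition share cell(s) cut to [0,1]"))
  }
  shL <- pmin(pmax(shL, 0), 1); shE <- pmin(pmax(shE, 0), 1); shV <- pmin(pmax(shV, 0), 1)
  L <- shL * st$D; E <- shE * st$D; V <- shV * st$D
  R <- st$D - L - E - V
  over <- R < 0
  if (any(over)) {
    idx <- which(over, arr.ind = TRUE)
    for (r in seq_len(min(nrow(idx), 50))) {
      clip("composition", st$countries[idx[r, 1]], st$years[idx[r, 2]],
           "staple remainder cut off at 0; groups rescaled")
    }
    scale <- st$D[over] / (L[over] + E[over] + V[over])
    L[over] <- L[over] * scale; E[over] <- E[over] * scale; V[over] <- V[over] * scale
    R[over] <- 0
  }
  st$L <- L; st$E <- E; st$V <- V; st$R <- R
  st$g <- L + E

  result$state <- st
  result$calibration <- calib
  result$clip_log <- dplyr::bind_rows(result$clip_log, clips)
  .state_tibbles(result)
}

# ---------------------------------------------------------------------------
# Counterfactuals
# ---------------------------------------------------------------------------

.cf_switches <- function() c("underweight_to_normal", "overweight_to_normal",
                             "inactive_to_moderate", "zero_waste")

#' Counterfactual change in global food demand
#'
#' Re-evaluates one timestep with a single hypothetical switch applied and
#' returns the percent change in global (population-weighted) food demand:
#' `underweight_to_normal` moves the underweight BMI-class share into the
#' normal class (adults 20-25, children -1..1 SD); `overweight_to_normal`
#' moves all overweight and obese shares likewise; `inactive_to_moderate`
#' gives the inactive population the active-lifestyle multiplier; and
#' `zero_waste` sets demand equal to intake, so its change is exactly
#' `-100 * X / D`.
#'
#' @param base An `ns_scenario` containing `year`.
#' @param switch One of `"underweight_to_normal"`, `"overweight_to_normal"`,
#'   `"inactive_to_moderate"`, `"zero_waste"`.
#' @param year Evaluation year.
#' @return List with `percent` (global percent change in demand), `switch`,
#'   `year` and a per-country tibble `by_country`.
#' @export
counterfactual <- function(base, switch, year) {
  stopifnot(inherits(base, "ns_scenario"))
  if (!switch %in% .cf_switches()) {
    stop("unknown counterfactual switch: ", switch,
         " (one of ", paste(.cf_switches(), collapse = ", "), ")")
  }
  st <- base$state
  k <- match(year, st$years)
  if (is.na(k)) stop("year ", year, " not in the scenario")
  C <- length(st$countries); nc <- length(st$cohorts)
  P <- array(st$P[, , , k], c(nc, 2, C))
  D <- st$D[, k]; I <- st$I[, k]; ratio <- st$ratio[, k]

  if (switch == "zero_waste") {
    Dp <- I
  } else {
    prep <- .engine_prep(base$params, base$standard)
    H <- array(st$H[, , , k], c(nc, 2, C))
    S <- lapply(st$S, function(a) array(a[, , , k], dim(a)[1:3]))
    A <- array(st$A[, , , k], c(3, 2, C))
    if (switch == "inactive_to_moderate") {
      A[] <- prep$act
    } else {
      move <- function(gi, from, to) {
        fi <- match(from, st$class_of[[gi]]); ti <- match(to, st$class_of[[gi]])
        add <- apply(S[[gi]][fi, , , drop = FALSE], c(2, 3), sum)
        S[[gi]][ti, , ] <- S[[gi]][ti, , ] + add
        S[[gi]][fi, , ] <- 0
        S[[gi]]
      }
      if (switch == "underweight_to_normal") {
        S[[1]] <- move(1, bmi_category_classes("child", "underweight"),
                       bmi_category_classes("child", "normal"))
        for (g in 2:3) S[[g]] <- move(g, bmi_category_classes("adult", "underweight"),
                                      bmi_category_classes("adult", "normal"))
      } else {
        S[[1]] <- move(1, bmi_category_classes("child", "overweight"),
                       bmi_category_classes("child", "normal"))
        for (g in 2:3) S[[g]] <- move(g, bmi_category_classes("adult", "overweight"),
                                      bmi_category_classes("adult", "normal"))
      }
    }
    Ip <- .engine_intake(prep, H, S, A, P)
    Dp <- D + ratio * (Ip - I)
  }
  popc <- apply(P, 3, sum)
  pct <- 100 * (sum(Dp * popc) - sum(D * popc)) / sum(D * popc)
  list(percent = pct, switch = switch, year = year,
       by_country = tibble::tibble(country = st$countries,
                                   demand_kcal = D, counterfactual_kcal = Dp,
                                   population = popc))
}

# ---------------------------------------------------------------------------
# Growth decomposition (chained / sequential substitution)
# ---------------------------------------------------------------------------

.decomp_factors <- function() c("population", "requirements", "bmi", "pal",
                                "waste", "composition")

.decomp_state <- function(result, k, prep) {
  st <- result$state
  C <- length(st$countries); nc <- length(st$cohorts)
  P <- array(st$P[, , , k], c(nc, 2, C))
  size <- apply(P, 3, sum)
  D <- st$D[, k]
  list(
    size = size,
    struct = P / rep(size, each = nc * 2),
    H = array(st$H[, , , k], c(nc, 2, C)),
    S = lapply(st$S, function(a) array(a[, , , k], dim(a)[1:3])),
    A = array(st$A[, , , k], c(3, 2, C)),
    ratio = st$ratio[, k],
    shL = st$L[, k] / D, shE = st$E[, k] / D, shV = st$V[, k] / D
  )
}

#' Decompose demand growth into its drivers
#'
#' Chained (sequential-substitution) decomposition of the change in a
#' demand aggregate between two timesteps into additive contributions of:
#' population size; food-energy requirements (demographic structure and
#' body height); BMI-class distribution; physical activity; household
#' waste; and dietary composition (the latter only affects food-group
#' aggregates such as animal calories). Factors are updated one at a time
#' in the given order, so contributions sum exactly to the net change;
#' the reversed order is always computed as well and the spread between
#' the two orders is reported. Optionally a Shapley decomposition
#' (average over all factor orders) is returned instead of the forward
#' chain.
#'
#' @param base An `ns_scenario`.
#' @param t0,t1 Start and end years (`t0 < t1`, both in the result).
#' @param variable `"demand"` (total, EJ/yr), `"animal"` (animal-source
#'   total, EJ/yr) or `"percap_demand"` (population-weighted kcal/cap/day).
#' @param factors Factor order; default
#'   population, requirements, bmi, pal, waste, composition.
#' @param region_map Optional tibble `country`, `region`; default one
#'   global region `"GLO"`.
#' @param shapley Average contributions over all factor orders?
#' @return Tibble of class `ns_decomposition` with columns `region`,
#'   `factor`, `contribution`, `contribution_reversed`, plus attributes
#'   `net` (named by region), `spread`, `variable` and `unit`.
#' @export
decompose_growth <- function(base, t0, t1,
                             variable = c("demand", "animal", "percap_demand"),
                             factors = .decomp_factors(), region_map = NULL,
                             shapley = FALSE) {
  stopifnot(inherits(base, "ns_scenario"))
  variable <- match.arg(variable)
  if (!setequal(factors, .decomp_factors())) {
    bad <- setdiff(factors, .decomp_factors())
    stop("unrecognized factor(s): ", paste(bad, collapse = ", "),
         " (expected a permutation of ", paste(.decomp_factors(), collapse = ", "), ")")
  }
  st <- base$state
  k0 <- match(t0, st$years); k1 <- match(t1, st$years)
  if (is.na(k0) || is.na(k1)) stop("t0/t1 must be years of the scenario")
  if (!(t0 < t1)) stop("t0 must precede t1")
  prep <- .engine_prep(base$params, base$standard)
  s0 <- .decomp_state(base, k0, prep)
  s1 <- .decomp_state(base, k1, prep)

  if (is.null(region_map)) {
    region_of <- rep("GLO", length(st$countries))
  } else {
    region_of <- region_map$region[match(st$countries, region_map$country)]
    if (anyNA(region_of)) {
      stop("region map misses countries: ",
           paste(st$countries[is.na(region_of)], collapse = ", "))
    }
  }
  regions <- sort(unique(region_of))
  nfac <- length(.decomp_factors())
  canon <- .decomp_factors()

  eval_mask <- function(mask) {
    pick <- function(name, field) {
      if (bitwAnd(mask, bitwShiftL(1L, match(name, canon) - 1L)) > 0L) s1[[field]] else s0[[field]]
    }
    size <- pick("population", "size")
    struct <- pick("requirements", "struct")
    H <- pick("requirements", "H")
    S <- pick("bmi", "S")
    A <- pick("pal", "A")
    ratio <- pick("waste", "ratio")
    I <- .engine_intake(prep, H, S, A, struct)
    D <- ratio * I
    val_c <- switch(variable,
      demand = D * size * .DAYS_PER_YEAR * .J_PER_KCAL / 1e18,
      animal = pick("composition", "shL") * D * size * .DAYS_PER_YEAR * .J_PER_KCAL / 1e18,
      percap_demand = D * size)
    v <- tapply(val_c, region_of, sum)
    if (variable == "percap_demand") v <- v / tapply(size, region_of, sum)
    v[regions]
  }

  cache <- new.env(parent = emptyenv())
  Fm <- function(mask) {
    key <- as.character(mask)
    if (is.null(cache[[key]])) cache[[key]] <- eval_mask(mask)
    cache[[key]]
  }

  chain <- function(ord) {
    contrib <- matrix(0, length(regions), nfac,
                      dimnames = list(regions, ord))
    mask <- 0L
    for (f in ord) {
      new_mask <- bitwOr(mask, bitwShiftL(1L, match(f, canon) - 1L))
      contrib[, f] <- Fm(new_mask) - Fm(mask)
      mask <- new_mask
    }
    contrib[, canon, drop = FALSE]
  }

  fwd <- chain(factors)
  rev_ <- chain(rev(factors))
  net <- Fm(bitwShiftL(1L, nfac) - 1L) - Fm(0L)

  if (shapley) {
    sh <- matrix(0, length(regions), nfac, dimnames = list(regions, canon))
    perms <- .permutations(factors)
    for (p in perms) sh <- sh + chain(p)
    fwd_out <- sh / length(perms)
  } else fwd_out <- fwd

  out <- tibble::tibble(
    region = rep(regions, times = nfac),
    factor = rep(canon, each = length(regions)),
    contribution = as.vector(fwd_out),
    contribution_reversed = as.vector(rev_)
  )
  structure(out, class = c("ns_decomposition", class(out)),
            net = net, spread = max(abs(fwd_out - rev_)),
            variable = variable,
            unit = if (variable == "percap_demand") "kcal/cap/day" else "EJ/yr",
            t0 = t0, t1 = t1, shapley = shapley)
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' @export
print.ns_decomposition <- function(x, ...) {
  cat("<ns_decomposition>", attr(x, "variable"), "growth", attr(x, "t0"), "->",
      attr(x, "t1"), "in", attr(x, "unit"),
      if (isTRUE(attr(x, "shapley"))) "(Shapley)" else "(chained)", "\n")
  print(tibble::as_tibble(x), n = Inf)
  cat("net:", paste(names(attr(x, "net")), signif(attr(x, "net"), 5),
                    sep = " = ", collapse = ", "),
      "| order spread:", signif(attr(x, "spread"), 3), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Aggregation and prevalence
# ---------------------------------------------------------------------------

#' Global (or regional) energy aggregates in EJ per year
#'
#' Converts per-capita kcal/day panels to annual totals:
#' `sum_c value_c * P_c * 365 * 4184 / 1e18` EJ/yr, per timestep and
#' optionally per region.
#'
#' @param result An `ns_scenario`.
#' @param region_map Optional tibble `country`, `region`. Must cover every
#'   country in the result; missing entries are an error.
#' @return Tibble with `year` (and `region`), population, and EJ/yr columns
#'   for demand, intake, waste and the four food groups.
#' @export
global_aggregate <- function(result, region_map = NULL) {
  st <- result$state
  C <- length(st$countries); TT <- length(st$years)
  popm <- apply(st$P, c(3, 4), sum)
  if (is.null(region_map)) {
    region_of <- rep("GLO", C)
  } else {
    region_of <- region_map$region[match(st$countries, region_map$country)]
    if (anyNA(region_of)) {
      stop("region map misses countries: ",
           paste(st$countries[is.na(region_of)], collapse = ", "))
    }
  }
  fac <- .DAYS_PER_YEAR * .J_PER_KCAL / 1e18
  agg <- function(mat) {
    tot <- rowsum((mat * popm) * fac, group = region_of)
    tot
  }
  pieces <- list(demand_EJ = agg(st$D), intake_EJ = agg(st$I), waste_EJ = agg(st$X),
                 animal_EJ = agg(st$L), empty_EJ = agg(st$E),
                 fvn_EJ = agg(st$V), staple_EJ = agg(st$R))
  popr <- rowsum(popm, group = region_of)
  regions <- rownames(popr)
  out <- tibble::tibble(
    region = rep(regions, times = TT),
    year = rep(st$years, each = length(regions)),
    population = as.vector(popr))
  for (nm in names(pieces)) out[[nm]] <- as.vector(pieces[[nm]])
  if (is.null(region_map)) out$region <- NULL
  out
}

#' Prevalence of underweight, overweight and obesity
#'
#' Population-weighted head counts and shares by BMI category, combining
#' the adult classes (overweight BMI >= 25, obese >= 30, underweight
#' < 18.5) with the child z-score bands (overweight > +1 SD, obese
#' > +2 SD, underweight < -2 SD). Overweight includes the obese.
#'
#' @param result An `ns_scenario`.
#' @param years Years to evaluate (default: all).
#' @return Tibble `year`, `category`, `persons`, `share`.
#' @export
bmi_prevalence <- function(result, years = NULL) {
  st <- result$state
  if (is.null(years)) years <- st$years
  grp_idx <- match(cohort_age_group(st$cohorts), age_groups())
  purrr::map(years, function(y) {
    k <- match(y, st$years)
    if (is.na(k)) stop("year ", y, " not in the scenario")
    C <- length(st$countries); nc <- length(st$cohorts)
    P <- array(st$P[, , , k], c(nc, 2, C))
    pop_grp <- array(0, c(3, 2, C))
    for (a in seq_len(nc)) pop_grp[grp_idx[a], , ] <- pop_grp[grp_idx[a], , ] + P[a, , ]
    total <- sum(P)
    count_cat <- function(category) {
      persons <- 0
      for (g in 1:3) {
        grp_kind <- if (g == 1) "child" else "adult"
        cls <- bmi_category_classes(grp_kind, category)
        bi <- match(cls, st$class_of[[g]])
        Sg <- array(st$S[[g]][, , , k], dim(st$S[[g]])[1:3])
        persons <- persons + sum(Sg[bi, , , drop = FALSE] *
                                   rep(pop_grp[g, , ], each = length(bi)))
      }
      persons
    }
    cats <- c("underweight", "overweight", "obese")
    tibble::tibble(
      year = y, category = cats,
      persons = vapply(cats, count_cat, 0),
      share = vapply(cats, count_cat, 0) / total)
  }) %>% dplyr::bind_rows()
}
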
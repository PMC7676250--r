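# ---------------------------------------------------------------------------
# Internal timestep engine. Panels are tibbles at the surface; inside the
# engine the state lives in dense arrays indexed [cohort, sex, country(, t)]
# so a full 30-country 1965-2100 run stays well under a second.
# ---------------------------------------------------------------------------

.slice2 <- function(arr, s) {
  # arr[b, sex, country] -> matrix [b, country] for one sex
  array(arr[, s, , drop = FALSE], dim = c(dim(arr)[1], dim(arr)[3]))
}

.engine_prep <- function(params, standard = growth_standard()) {
  .check_params(params)
  cohorts <- age_cohorts()
  mid <- cohort_midpoints()
  groups <- age_groups()
  grp_idx <- match(cohort_age_group(cohorts), groups)

  sch <- params$schofield
  lut_g <- stats::setNames(sch$gamma_kcal_per_kg, paste(sch$bracket, sch$sex))
  lut_d <- stats::setNames(sch$delta_kcal, paste(sch$bracket, sch$sex))
  gam <- del <- matrix(0, length(cohorts), 2, dimnames = list(cohorts, sexes()))
  for (s in 1:2) {
    key <- paste(schofield_bracket(cohorts), sexes()[s])
    gam[, s] <- lut_g[key]
    del[, s] <- lut_d[key]
  }

  adult_tbl <- bmi_class_table("adult")
  child_tbl <- bmi_class_table("child")
  child_idx <- which(mid < 15)
  child_pos <- match(seq_along(cohorts), child_idx)
  child_B <- array(0, c(nrow(child_tbl), length(child_idx), 2))
  std_child <- matrix(0, length(child_idx), 2)
  std18 <- numeric(2)
  for (s in 1:2) {
    medb <- .std_bmi_lookup(standard, sexes()[s], mid[child_idx])
    for (ci in seq_along(child_idx)) {
      child_B[, ci, s] <- medb[ci] *
        (1 + params$child_bmi_sd_frac * child_tbl$representative_z)
    }
    std_child[, s] <- .std_lookup(standard, sexes()[s], mid[child_idx])
    std18[s] <- .std_lookup(standard, sexes()[s], 18)
  }

  class_of <- list(child_tbl$bmi_class, adult_tbl$bmi_class, adult_tbl$bmi_class)
  nb_of <- vapply(class_of, length, 0L)
  bmi_base <- bmi_delta <- bmi_k <- vector("list", 3)
  for (g in 1:3) {
    nb <- nb_of[g]
    base <- delta <- kk <- matrix(NA_real_, nb, 2)
    for (s in 1:2) {
      cur <- params$bmi[params$bmi$age_group == groups[g] &
                          params$bmi$sex == sexes()[s], ]
      ord <- match(class_of[[g]], cur$bmi_class)
      if (anyNA(ord)) stop("missing BMI share parameters for ", groups[g], "/", sexes()[s])
      base[, s] <- cur$base[ord]
      delta[, s] <- cur$delta[ord]
      kk[, s] <- cur$halfsat[ord]
    }
    bmi_base[[g]] <- base; bmi_delta[[g]] <- delta; bmi_k[[g]] <- kk
  }

  pal_base <- pal_delta <- pal_k <- matrix(NA_real_, 3, 2)
  for (g in 1:3) for (s in 1:2) {
    row <- params$pal$curve[params$pal$curve$age_group == groups[g] &
                              params$pal$curve$sex == sexes()[s], ]
    if (nrow(row) != 1) stop("missing PAL curve for ", groups[g], "/", sexes()[s])
    pal_base[g, s] <- row$base; pal_delta[g, s] <- row$delta; pal_k[g, s] <- row$halfsat
  }

  list(params = params, cohorts = cohorts, mid = mid, groups = groups,
       grp_idx = grp_idx, gam = gam, del = del,
       adult_B = adult_tbl$representative_bmi, child_B = child_B,
       child_idx = child_idx, child_pos = child_pos,
       std_child = std_child, std18 = std18,
       class_of = class_of, nb_of = nb_of,
       bmi_base = bmi_base, bmi_delta = bmi_delta, bmi_k = bmi_k,
       pal_base = pal_base, pal_delta = pal_delta, pal_k = pal_k,
       alpha = stats::setNames(params$height$alpha, params$height$sex),
       beta = stats::setNames(params$height$beta, params$height$sex),
       sed = params$pal$sedentary, act = params$pal$active,
       eps = params$waste[["epsilon"]], zeta = params$waste[["zeta"]],
       diet = params$diet, N = params$pregnancy_kcal)
}

.engine_shares <- function(prep, Y) {
  C <- length(Y)
  lapply(1:3, function(g) {
    nb <- prep$nb_of[g]
    S <- array(0, c(nb, 2, C))
    for (s in 1:2) {
      raw <- matrix(0, nb, C)
      for (b in seq_len(nb)) {
        k <- prep$bmi_k[[g]][b, s]
        sat <- if (is.na(k)) 0 else Y / (k + Y)
        raw[b, ] <- prep$bmi_base[[g]][b, s] + prep$bmi_delta[[g]][b, s] * sat
      }
      raw <- pmin(pmax(raw, 0), 1)
      tot <- colSums(raw)
      if (any(tot <= 0)) stop("all BMI shares zero after clipping; cannot normalize")
      S[, s, ] <- sweep(raw, 2, tot, "/")
    }
    S
  })
}

.engine_pal <- function(prep, Y) {
  C <- length(Y)
  p <- array(0, c(3, 2, C))
  for (g in 1:3) for (s in 1:2) {
    p[g, s, ] <- pmin(pmax(
      prep$pal_base[g, s] + prep$pal_delta[g, s] * Y / (prep$pal_k[g, s] + Y), 0), 1)
  }
  list(p = p, A = p * prep$sed + (1 - p) * prep$act)
}

.engine_intake <- function(prep, H, S, A, P) {
  C <- dim(H)[3]
  num <- numeric(C)
  den <- numeric(C)
  for (a in seq_along(prep$cohorts)) {
    g <- prep$grp_idx[a]
    for (s in 1:2) {
      B <- if (g == 1) prep$child_B[, prep$child_pos[a], s] else prep$adult_B
      nb <- length(B)
      h2 <- (H[a, s, ] / 100)^2
      W <- outer(B, h2)
      Im <- (prep$gam[a, s] * W + prep$del[a, s]) * rep(A[g, s, ], each = nb)
      Sm <- .slice2(S[[g]], s)
      num <- num + colSums(Im * Sm) * P[a, s, ]
      den <- den + P[a, s, ]
    }
  }
  if (any(den <= 0)) stop("zero total population in at least one country")
  newborn <- P[1, 1, ] + P[1, 2, ]
  num / den + prep$N * (newborn / 5) / den
}

.engine_height <- function(prep, h15, H_prev = NULL) {
  # h15: matrix [2, C] (sex x country)
  C <- ncol(h15)
  H <- array(NA_real_, c(length(prep$cohorts), 2, C))
  adult_idx <- which(prep$mid >= 20)
  i15 <- which(names(prep$mid) == "15-19")
  for (s in 1:2) {
    for (ci in seq_along(prep$child_idx)) {
      H[prep$child_idx[ci], s, ] <- prep$std_child[ci, s] * h15[s, ] / prep$std18[s]
    }
    H[i15, s, ] <- h15[s, ]
    if (is.null(H_prev)) {
      for (a in adult_idx) H[a, s, ] <- h15[s, ]
    } else {
      for (a in adult_idx) H[a, s, ] <- H_prev[a - 1L, s, ]
    }
  }
  H
}

.engine_year <- function(prep, Y, P, H) {
  S <- .engine_shares(prep, Y)
  palst <- .engine_pal(prep, Y)
  I <- .engine_intake(prep, H, S, palst$A, P)
  ratio <- prep$eps * Y / (prep$zeta + Y) + 1
  D <- ratio * I
  X <- D - I
  shL <- .tree_share(Y, prep$diet$asymptote[prep$diet$group == "animal"],
                     prep$diet$halfsat[prep$diet$group == "animal"])
  shE <- .tree_share(Y, prep$diet$asymptote[prep$diet$group == "empty"],
                     prep$diet$halfsat[prep$diet$group == "empty"])
  shV <- .tree_share(Y, prep$diet$asymptote[prep$diet$group == "fruitveg"],
                     prep$diet$halfsat[prep$diet$group == "fruitveg"])
  L <- shL * D
  E <- shE * (D - L)
  V <- shV * (D - L - E)
  R <- D - L - E - V
  list(S = S, p = palst$p, A = palst$A, I = I, ratio = ratio, D = D, X = X,
       L = L, E = E, V = V, R = R, g = L + E)
}

.drivers_matrices <- function(drivers, years) {
  countries <- sort(unique(drivers$income$country))
  inc <- drivers$income
  Y <- matrix(NA_real_, length(countries), length(years),
              dimnames = list(countries, years))
  Y[cbind(match(inc$country, countries), match(inc$year, years))] <- inc$income
  if (anyNA(Y)) {
    gaps <- which(is.na(Y), arr.ind = TRUE)
    stop("income panel has gaps: ",
         paste(utils::head(paste(countries[gaps[, 1]], years[gaps[, 2]], sep = "/"), 5),
               collapse = ", "),
         if (nrow(gaps) > 5) paste0(" (+", nrow(gaps) - 5, " more)"))
  }
  pop <- drivers$population
  cohorts <- age_cohorts()
  P <- array(NA_real_, c(length(cohorts), 2, length(countries), length(years)),
             dimnames = list(cohorts, sexes(), countries, years))
  P[cbind(match(pop$age, cohorts), match(pop$sex, sexes()),
          match(pop$country, countries), match(pop$year, years))] <- pop$population
  if (anyNA(P)) {
    n_gap <- sum(is.na(P))
    stop("population panel has ", n_gap, " missing cohort cells on the run grid")
  }
  list(countries = countries, Y = Y, P = P)
}
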
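#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr %>% arrange bind_rows case_when distinct filter full_join
#'   group_by inner_join left_join mutate n pull rename select slice summarise
#'   ungroup anti_join across all_of
#' @importFrom rlang .data
#' @importFrom stats approx coef lm median qlogis plogis rnorm runif sd setNames
#'   var vcov
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Index conventions: 5-year timestep grid, age cohorts, sexes, BMI classes.
# ---------------------------------------------------------------------------

#' Simulation timestep grid
#'
#' The model runs on a fixed grid of 5-year timesteps labelled by their
#' representative calendar year, 1965 through 2100 (28 steps).
#'
#' @return Integer vector of timestep years.
#' @export
#' @examples
#' timestep_grid()
timestep_grid <- function() seq(1965L, 2100L, by = 5L)

#' Age cohort labels
#'
#' Twenty 5-year age cohorts `0-4` ... `95-99` plus an open-ended `100+`
#' cohort. Cohorts partition ages with no overlap; cohort ageing moves one
#' class per 5-year timestep.
#'
#' @return Character vector of 21 cohort labels.
#' @export
age_cohorts <- function() {
  lo <- seq(0L, 95L, by = 5L)
  c(paste0(lo, "-", lo + 4L), "100+")
}

#' Midpoint age of each cohort (the open 100+ cohort uses 102.5)
#' @return Named numeric vector keyed by cohort label.
#' @export
cohort_midpoints <- function() {
  stats::setNames(c(seq(2.5, 97.5, by = 5), 102.5), age_cohorts())
}

#' Sexes used throughout the model
#' @return Character vector `c("male", "female")`.
#' @export
sexes <- function() c("male", "female")

#' Broad age groups used for BMI shares and physical activity
#'
#' Children (0-14), working-age adults (15-59) and retirement-age adults
#' (60+). BMI-class shares and activity levels are resolved at this
#' granularity; intake is computed per 5-year cohort.
#'
#' @return Character vector of age-group labels.
#' @export
age_groups <- function() c("0-14", "15-59", "60+")

#' Map a 5-year cohort to its broad age group
#' @param cohort Character vector of cohort labels.
#' @return Character vector of age-group labels.
#' @export
cohort_age_group <- function(cohort) {
  mid <- cohort_midpoints()[cohort]
  if (anyNA(mid)) stop("unknown age cohort: ", paste(cohort[is.na(mid)], collapse = ", "))
  dplyr::case_when(mid < 15 ~ "0-14", mid < 60 ~ "15-59", TRUE ~ "60+")
}

#' BMI class definitions
#'
#' Adults (15+) use six absolute BMI classes; children (0-14) use five
#' classes expressed as z-score bands around the growth-standard median.
#' Each class carries a representative BMI used to convert height to body
#' weight: adult classes use interval midpoints (open tails use the midpoint
#' of a 5-unit tail), child classes carry a representative z-score that is
#' mapped to BMI via the growth-standard median BMI (one SD taken as 10% of
#' the median).
#'
#' @param group `"adult"` or `"child"`.
#' @return Tibble with columns `bmi_class`, `lower`, `upper` and either
#'   `representative_bmi` (adult, kg/m2) or `representative_z` (child, SD).
#' @export
#' @examples
#' bmi_class_table("adult")
bmi_class_table <- function(group = c("adult", "child")) {
  group <- match.arg(group)
  if (group == "adult") {
    tibble::tibble(
      bmi_class = c("<18.5", "18.5-20", "20-25", "25-30", "30-35", "35+"),
      lower = c(-Inf, 18.5, 20, 25, 30, 35),
      upper = c(18.5, 20, 25, 30, 35, Inf),
      representative_bmi = c(17.5, 19.25, 22.5, 27.5, 32.5, 37.5)
    )
  } else {
    tibble::tibble(
      bmi_class = c("<-2sd", "-2--1sd", "-1-1sd", "1-2sd", ">2sd"),
      lower = c(-Inf, -2, -1, 1, 2),
      upper = c(-2, -1, 1, 2, Inf),
      representative_z = c(-2.5, -1.5, 0, 1.5, 2.5)
    )
  }
}

#' Which BMI classes count as underweight / overweight / obese
#'
#' Adult overweight is BMI >= 25 and obesity BMI >= 30; child bands use the
#' growth-standard z-score convention (underweight below -2 SD, overweight
#' above +1 SD, obesity above +2 SD).
#'
#' @param group `"adult"` or `"child"`.
#' @param category One of `"underweight"`, `"normal"`, `"overweight"`,
#'   `"obese"`. Overweight includes obese classes.
#' @return Character vector of class labels.
#' @export
bmi_category_classes <- function(group, category) {
  adult <- list(
    underweight = "<18.5", normal = "20-25",
    overweight = c("25-30", "30-35", "35+"), obese = c("30-35", "35+")
  )
  child <- list(
    underweight = "<-2sd", normal = "-1-1sd",
    overweight = c("1-2sd", ">2sd"), obese = ">2sd"
  )
  tbl <- if (group == "adult") adult else child
  out <- tbl[[category]]
  if (is.null(out)) stop("unknown BMI category: ", category)
  out
}

# ---------------------------------------------------------------------------
# Unit conversions
# ---------------------------------------------------------------------------

#' Convert kilocalories to joules
#'
#' Uses the fixed thermochemical convention 1 kcal = 4184 J. The package
#' works in kcal/cap/day internally; joules appear only at reporting
#' boundaries (Exajoule aggregates of national totals).
#'
#' @param kcal Numeric vector of energies in kcal.
#' @return Energies in joules.
#' @export
#' @examples
#' kcal_to_joules(1)     # 4184
#' kcal_to_joules(2400) * 365 * 1e9 / 1e18  # ~3.67 EJ/yr for 1e9 people
kcal_to_joules <- function(kcal) {
  stopifnot(is.numeric(kcal))
  kcal * 4184
}

#' Joules per kcal and days per year used in EJ aggregation
#' @keywords internal
.J_PER_KCAL <- 4184
.DAYS_PER_YEAR <- 365

# ---------------------------------------------------------------------------
# Panel schemas + validation
# ---------------------------------------------------------------------------

.panel_schemas <- function() {
  list(
    income       = c("country", "year", "income"),
    population   = c("country", "year", "age", "sex", "population"),
    height       = c("country", "year", "age", "sex", "height_cm"),
    bmi_shares   = c("country", "year", "age_group", "sex", "bmi_class", "share"),
    demand       = c("country", "year", "demand_kcal"),
    composition  = c("country", "year", "animal_kcal", "empty_kcal",
                     "fvn_kcal", "staple_kcal", "total_kcal"),
    diet_quality = c("country", "year", "g_kcal"),
    growth_standard = c("age", "sex", "height_cm", "median_bmi"),
    schofield    = c("bracket", "sex", "gamma_kcal_per_kg", "delta_kcal")
  )
}

#' Panel kinds understood by the data model
#' @return Character vector of panel kind names.
#' @export
panel_kinds <- function() names(.panel_schemas())

.violation <- function(rule, detail) tibble::tibble(rule = rule, detail = detail)

#' Validate a long-format panel
#'
#' Checks a panel against its declared kind: required columns, off-grid
#' timestep years, negative quantities, missing country-year cells within
#' the panel's own country and year sets, and (for BMI shares) per-stratum
#' sums deviating from 1 by more than `share_tol`. Validation is
#' side-effect free and idempotent.
#'
#' @param panel A data frame.
#' @param kind One of [panel_kinds()].
#' @param share_tol Tolerance on share sums (default 1e-6).
#' @return A tibble of violations with columns `rule` and `detail`;
#'   zero rows means the panel is valid.
#' @export
#' @examples
#' ok <- tibble::tibble(country = "A", year = 1965, income = 500)
#' validate_panel(ok, "income")
validate_panel <- function(panel, kind, share_tol = 1e-6) {
  schemas <- .panel_schemas()
  if (!kind %in% names(schemas)) {
    stop("unknown panel kind: ", kind, " (known: ",
         paste(names(schemas), collapse = ", "), ")")
  }
  cols <- schemas[[kind]]
  out <- list()
  missing_cols <- setdiff(cols, names(panel))
  if (length(missing_cols)) {
    return(.violation("missing_columns", paste(missing_cols, collapse = ", ")))
  }
  panel <- tibble::as_tibble(panel)

  if ("year" %in% cols) {
    bad <- setdiff(unique(panel$year), timestep_grid())
    if (length(bad)) {
      out <- c(out, list(.violation("off_grid_year", paste(sort(bad), collapse = ", "))))
    }
  }
  if ("age" %in% cols && kind != "growth_standard") {
    bad <- setdiff(unique(panel$age), age_cohorts())
    if (length(bad)) {
      out <- c(out, list(.violation("unknown_age_cohort", paste(bad, collapse = ", "))))
    }
  }
  if ("sex" %in% cols) {
    bad <- setdiff(unique(panel$sex), sexes())
    if (length(bad)) {
      out <- c(out, list(.violation("unknown_sex", paste(bad, collapse = ", "))))
    }
  }

  value_cols <- setdiff(cols, c("country", "year", "age", "sex", "age_group",
                                "bmi_class", "bracket"))
  for (vc in value_cols) {
    v <- panel[[vc]]
    if (anyNA(v)) {
      idx <- which(is.na(v))
      out <- c(out, list(.violation(
        "not_available",
        paste0(vc, " NA in ", length(idx), " cell(s), first at row ", idx[1])
      )))
    }
    allow_negative <- vc %in% c("delta_kcal")
    neg <- which(!is.na(v) & v < 0 & !allow_negative)
    if (length(neg)) {
      key_cols <- intersect(c("country", "year", "age", "sex", "bmi_class"), names(panel))
      first <- paste(unlist(panel[neg[1], key_cols]), collapse = "/")
      out <- c(out, list(.violation(
        "negative_value",
        paste0(vc, " < 0 in ", length(neg), " cell(s), first at ", first)
      )))
    }
    inf <- which(!is.finite(v) & !is.na(v))
    if (length(inf)) {
      out <- c(out, list(.violation("non_finite", paste0(vc, " non-finite at row ", inf[1]))))
    }
  }

  # completeness: every country must cover every year present in the panel
  if (all(c("country", "year") %in% cols)) {
    grid <- tidyr::expand_grid(country = unique(panel$country), year = unique(panel$year))
    have <- dplyr::distinct(panel, .data$country, .data$year)
    gaps <- dplyr::anti_join(grid, have, by = c("country", "year"))
    if (nrow(gaps)) {
      out <- c(out, list(.violation(
        "missing_cell",
        paste0(nrow(gaps), " missing country-year cell(s), first ",
               gaps$country[1], "/", gaps$year[1])
      )))
    }
  }

  if (kind == "bmi_shares") {
    sums <- panel %>%
      dplyr::group_by(.data$country, .data$year, .data$age_group, .data$sex) %>%
      dplyr::summarise(s = sum(.data$share), .groups = "drop") %>%
      dplyr::filter(abs(.data$s - 1) > share_tol)
    if (nrow(sums)) {
      out <- c(out, list(.violation(
        "share_sum",
        paste0(nrow(sums), " stratum/strata with share sum != 1, first ",
               sums$country[1], "/", sums$year[1], "/", sums$age_group[1], "/",
               sums$sex[1], " (sum ", signif(sums$s[1], 6), ")")
      )))
    }
  }
  if (kind == "composition") {
    resid <- with(panel, abs(animal_kcal + empty_kcal + fvn_kcal + staple_kcal - total_kcal))
    bad <- which(resid > pmax(1e-9 * abs(panel$total_kcal), 1e-9))
    if (length(bad)) {
      out <- c(out, list(.violation(
        "composition_sum",
        paste0(length(bad), " row(s) where groups do not sum to total, first row ", bad[1])
      )))
    }
  }
  if (length(out)) dplyr::bind_rows(out) else .violation(character(), character())
}

# ---------------------------------------------------------------------------
# Panel I/O (long CSV, UTF-8, "." decimal)
# ---------------------------------------------------------------------------

#' Read a panel CSV
#'
#' Panels are long-format CSV files with the column sets listed by the
#' package schema (see [panel_schema()]). Values round-trip bit-identically
#' for decimal representations up to full double precision.
#'
#' @param path File path.
#' @param kind One of [panel_kinds()]; used to validate after reading.
#' @param validate Stop if the panel has violations? Default TRUE.
#' @return A tibble.
#' @export
read_panel <- function(path, kind, validate = TRUE) {
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (validate) {
    v <- validate_panel(panel, kind)
    if (nrow(v)) {
      stop("invalid ", kind, " panel ", path, ": ",
           paste(v$rule, v$detail, sep = ": ", collapse = "; "))
    }
  }
  panel
}

#' Write a panel CSV
#' @param panel Data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' Machine-readable panel schema
#'
#' Returns (and optionally writes) the table of panel kinds, their columns
#' and units that ships with the package (`inst/extdata/schema.csv`).
#'
#' @return Tibble with columns `kind`, `column`, `unit`.
#' @export
panel_schema <- function() {
  path <- system.file("extdata", "schema.csv", package = "nutrisim")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
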
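test_that("a full scenario run satisfies every cell-wise invariant", {
  base <- baseline_of(world_noiseless_small())

  sums <- base$bmi_shares |>
    dplyr::group_by(country, year, age_group, sex) |>
    dplyr::summarise(s = sum(share), .groups = "drop")
  expect_lt(max(abs(sums$s - 1)), 1e-12)

  en <- base$energy
  expect_true(all(en$intake_kcal > 0))
  expect_true(all(en$demand_kcal >= en$intake_kcal))
  expect_true(all(abs(en$waste_kcal - (en$demand_kcal - en$intake_kcal)) < 1e-9))

  comp <- base$composition
  resid <- abs(comp$animal_kcal + comp$empty_kcal + comp$fvn_kcal +
                 comp$staple_kcal - comp$total_kcal)
  expect_true(all(resid <= 1e-12 * comp$total_kcal))
  expect_true(all(comp$staple_kcal >= 0))
  expect_equal(comp$total_kcal, en$demand_kcal)

  expect_true(all(base$pal$pal >= 1.2 & base$pal$pal <= 2.5))
  expect_true(all(base$height$height_cm > 0))
})

test_that("adult cohort heights shift one age class per timestep", {
  base <- baseline_of(world_noiseless_small())
  h <- base$height
  cohorts <- age_cohorts()
  adult <- cohorts[cohort_midpoints() >= 20]
  prev <- cohorts[match(adult, cohorts) - 1]
  for (yr in c(1990, 2050)) {
    a <- h[h$year == yr, ]
    b <- h[h$year == yr + 5, ]
    key <- function(d) paste(d$country, d$sex, d$age)
    now <- b$height_cm[match(paste(b$country[1], "male", adult)[1:5], key(b))]
    was <- a$height_cm[match(paste(b$country[1], "male", prev)[1:5], key(a))]
    expect_equal(now, was)
  }
})

test_that("constant drivers give a stationary simulation", {
  drv <- constant_drivers(n = 2, income = 6000)
  res <- run_scenario(drv)
  en <- res$energy
  first <- en[en$year == min(en$year), ]
  last <- en[en$year == max(en$year), ]
  expect_equal(last$demand_kcal, first$demand_kcal, tolerance = 1e-9)
  expect_equal(last$intake_kcal, first$intake_kcal, tolerance = 1e-9)
  h <- res$height
  expect_equal(h$height_cm[h$year == max(h$year)],
               h$height_cm[h$year == min(h$year)], tolerance = 1e-9)
})

test_that("per-capita outputs are invariant to population scale", {
  drv <- constant_drivers(n = 2, income = 3000)
  drv2 <- drv
  drv2$population$population <- drv2$population$population * 2
  r1 <- run_scenario(drv)
  r2 <- run_scenario(drv2)
  expect_equal(r2$energy$demand_kcal, r1$energy$demand_kcal)
  expect_equal(r2$composition$animal_kcal, r1$composition$animal_kcal)
  expect_equal(r2$height$height_cm, r1$height$height_cm)
  # totals double
  expect_equal(global_aggregate(r2)$demand_EJ,
               2 * global_aggregate(r1)$demand_EJ)
})

test_that("repeated runs are bit-identical and gaps are reported", {
  w <- world_noiseless_small()
  r1 <- run_scenario(w$drivers)
  r2 <- run_scenario(w$drivers)
  expect_identical(r1$energy, r2$energy)
  expect_identical(r1$state$H, r2$state$H)

  broken <- w$drivers
  broken$income <- broken$income[-3, ]
  expect_error(run_scenario(broken), "gaps")
})

test_that("calibration reproduces reported values exactly at the calibration year", {
  w <- world_noiseless_small()
  # deliberately mis-specified parameters, calibrated back to the truth run
  p2 <- default_parameters()
  p2$waste[["epsilon"]] <- 0.30
  p2$height$alpha <- c(112, 105)
  p2$diet$asymptote <- c(0.40, 0.30, 0.20)
  mod <- run_scenario(w$drivers, p2)
  cal <- calibrate(mod, w$observations, year = 2010)
  out <- apply_calibration(mod, cal)

  at <- function(p) dplyr::filter(p, year == 2010)
  d <- dplyr::inner_join(at(out$energy), at(w$observations$demand), by = "country")
  expect_equal(d$demand_kcal.x, d$demand_kcal.y, tolerance = 1e-12)
  h <- dplyr::inner_join(at(out$height), at(w$observations$height),
                         by = c("country", "age", "sex"))
  expect_equal(h$height_cm.x, h$height_cm.y, tolerance = 1e-12)
  s <- dplyr::inner_join(at(out$bmi_shares), at(w$observations$bmi_shares),
                         by = c("country", "age_group", "sex", "bmi_class"))
  expect_equal(s$share.x, s$share.y, tolerance = 1e-12)
  cmp <- dplyr::inner_join(at(out$composition), at(w$observations$composition),
                           by = "country")
  expect_equal(cmp$animal_kcal.x, cmp$animal_kcal.y, tolerance = 1e-9)
  expect_equal(cmp$staple_kcal.x, cmp$staple_kcal.y, tolerance = 1e-9)
  expect_equal(nrow(out$clip_log), 0)
})

test_that("calibration cutoffs clip shares into [0,1] and log the event", {
  w <- world_noiseless_small()
  mod <- run_scenario(w$drivers)
  # force an offset that pushes one class share above 1
  cal <- structure(list(
    year = 2010,
    bmi_shares = tibble::tibble(
      country = w$drivers$income$country[1], age_group = "15-59", sex = "male",
      bmi_class = "20-25", offset = 0.8)), class = "ns_calibration")
  out <- apply_calibration(mod, cal)
  expect_gt(nrow(out$clip_log), 0)
  expect_true(any(grepl("cut to \\[0,1\\]", out$clip_log$detail)))
  sums <- out$bmi_shares |>
    dplyr::group_by(country, year, age_group, sex) |>
    dplyr::summarise(s = sum(share), .groups = "drop")
  expect_lt(max(abs(sums$s - 1)), 1e-12)
  expect_true(all(out$bmi_shares$share >= 0 & out$bmi_shares$share <= 1))

  # demand offsets below intake are floored at intake (zero waste) and logged
  cal2 <- structure(list(
    year = 2010,
    demand = tibble::tibble(country = unique(w$drivers$income$country)[1],
                            offset = -1e5)), class = "ns_calibration")
  out2 <- apply_calibration(mod, cal2)
  expect_true(all(out2$energy$demand_kcal >= out2$energy$intake_kcal))
  expect_true(any(grepl("cut off at intake", out2$clip_log$detail)))
})

test_that("counterfactual switches have the expected signs and identities", {
  base <- baseline_of(world_noiseless_small())
  yr <- 2010
  cf <- function(sw) counterfactual(base, sw, yr)$percent
  expect_gte(cf("underweight_to_normal"), 0)
  expect_lt(cf("overweight_to_normal"), 0)
  expect_gte(cf("inactive_to_moderate"), 0)
  expect_lt(cf("zero_waste"), 0)

  # zero-waste change equals -100 X / D exactly (global, population-weighted)
  st <- base$state
  k <- match(yr, st$years)
  popc <- apply(array(st$P[, , , k], dim(st$P)[1:3]), 3, sum)
  expect_equal(cf("zero_waste"),
               -100 * sum(st$X[, k] * popc) / sum(st$D[, k] * popc))
  expect_error(counterfactual(base, "teleportation", yr), "unknown")
  expect_error(counterfactual(base, "zero_waste", 1234), "not in the scenario")
})

test_that("counterfactuals are no-ops when the targeted group is empty", {
  p <- default_parameters()
  # move all underweight baseline mass into the normal class, no income trend
  for (g in unique(paste(p$bmi$age_group, p$bmi$sex))) {
    rows <- paste(p$bmi$age_group, p$bmi$sex) == g
    cls <- p$bmi$bmi_class[rows]
    uw <- cls %in% c("<18.5", "<-2sd")
    nm <- cls %in% c("20-25", "-1-1sd")
    p$bmi$base[rows][nm] <- p$bmi$base[rows][nm] + sum(p$bmi$base[rows][uw])
    p$bmi$delta[rows][nm] <- p$bmi$delta[rows][nm] + sum(p$bmi$delta[rows][uw])
    p$bmi$base[rows][uw] <- 0
    p$bmi$delta[rows][uw] <- 0
  }
  res <- run_scenario(constant_drivers(n = 2, income = 5000), p)
  expect_equal(counterfactual(res, "underweight_to_normal", 2000)$percent, 0)
})

test_that("growth decomposition is additive and attributes single factors fully", {
  base <- baseline_of(world_noiseless_small())
  dec <- decompose_growth(base, 1990, 2060)
  expect_equal(sum(dec$contribution), unname(attr(dec, "net")),
               tolerance = 1e-12)
  expect_equal(sum(dec$contribution_reversed), unname(attr(dec, "net")),
               tolerance = 1e-12)
  # composition cannot move total demand
  expect_equal(dec$contribution[dec$factor == "composition"], 0)
  dec_a <- decompose_growth(base, 1990, 2060, variable = "animal")
  expect_equal(sum(dec_a$contribution), unname(attr(dec_a, "net")),
               tolerance = 1e-12)
  expect_true(abs(dec_a$contribution[dec_a$factor == "composition"]) > 0)
  expect_error(decompose_growth(base, 1990, 2060, factors = c("magic")),
               "unrecognized")
  expect_error(decompose_growth(base, 2060, 1990), "precede")
})

test_that("pure population growth is attributed entirely to population", {
  drv <- constant_drivers(n = 2, income = 5000, pop_growth = 1.2)
  res <- run_scenario(drv)
  dec <- decompose_growth(res, 1990, 2020)
  pop_c <- dec$contribution[dec$factor == "population"]
  other <- dec$contribution[dec$factor != "population"]
  expect_equal(pop_c, unname(attr(dec, "net")), tolerance = 1e-9)
  expect_equal(max(abs(other)), 0, tolerance = 1e-12)
})

test_that("Shapley decomposition also sums to the net change", {
  base <- baseline_of(world_noiseless_small())
  dec <- decompose_growth(base, 2000, 2030, shapley = TRUE)
  expect_equal(sum(dec$contribution), unname(attr(dec, "net")),
               tolerance = 1e-10)
})

test_that("global aggregation converts kcal/cap/day to EJ/yr and partitions by region", {
  base <- baseline_of(world_noiseless_small())
  glo <- global_aggregate(base)
  # independent recomputation from the long panels
  pop <- base$drivers$population |>
    dplyr::group_by(country, year) |>
    dplyr::summarise(pop = sum(population), .groups = "drop")
  manual <- dplyr::inner_join(base$energy, pop, by = c("country", "year")) |>
    dplyr::group_by(year) |>
    dplyr::summarise(ej = sum(demand_kcal * pop) * 365 * 4184 / 1e18,
                     .groups = "drop")
  expect_equal(glo$demand_EJ, manual$ej, tolerance = 1e-12)
  # single-country hand value: 2400 kcal/cap/day for 1e9 people ~ 3.67 EJ
  expect_equal(2400 * 1e9 * 365 * 4184 / 1e18, 3.665184)

  countries <- unique(base$energy$country)
  rmap <- tibble::tibble(country = countries,
                         region = rep(c("R1", "R2"), length.out = length(countries)))
  reg <- global_aggregate(base, rmap)
  by_year <- reg |> dplyr::group_by(year) |>
    dplyr::summarise(ej = sum(demand_EJ), .groups = "drop")
  expect_equal(by_year$ej, glo$demand_EJ, tolerance = 1e-12)
  expect_error(global_aggregate(base, rmap[-1, ]), "misses")
})

test_that("prevalence summaries track the nutrition transition", {
  base <- baseline_of(world_noiseless_small())
  prev <- bmi_prevalence(base, c(1965, 2050))
  expect_true(all(prev$share >= 0 & prev$share <= 1))
  ow <- prev[prev$category == "overweight", ]
  uw <- prev[prev$category == "underweight", ]
  ob <- prev[prev$category == "obese", ]
  # incomes rise over the synthetic transition: overweight up, underweight down
  expect_gt(ow$share[ow$year == 2050], ow$share[ow$year == 1965])
  expect_lt(uw$share[uw$year == 2050], uw$share[uw$year == 1965])
  # obese is a subset of overweight
  expect_true(all(ob$persons <= ow$persons))
})
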
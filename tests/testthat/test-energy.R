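test_that("cohorts map to Schofield brackets by midpoint age", {
  expect_equal(schofield_bracket(c("0-4", "5-9", "10-14", "15-19", "20-24",
                                   "25-29", "30-34", "55-59", "60-64", "100+")),
               c("0-3", "3-10", "10-18", "10-18", "18-30", "18-30",
                 "30-60", "30-60", "60+", "60+"))
  expect_error(schofield_bracket("200+"), "unmapped")
})

test_that("bmr matches the Schofield coefficient table (MJ-table oracle)", {
  # independent hand computation from the published MJ/day coefficients
  mj <- function(g, d, w) (g * w + d) * 1000 / 4.184
  expect_equal(bmr(70, "30-34", "male"), mj(0.048, 3.653, 70), tolerance = 1e-9)
  expect_lt(abs(bmr(70, "30-34", "male") - 1676), 0.5)
  expect_equal(bmr(55, "20-24", "female"), mj(0.062, 2.036, 55), tolerance = 1e-9)
  expect_equal(bmr(12, "0-4", "male"), mj(0.249, -0.127, 12), tolerance = 1e-9)
  expect_equal(bmr(60, "70-74", "female"), mj(0.038, 2.755, 60), tolerance = 1e-9)
})

test_that("bmr limits and monotonicity", {
  cf <- schofield_table()
  d <- cf$delta_kcal[cf$bracket == "30-60" & cf$sex == "male"]
  expect_equal(bmr(0, "30-34", "male"), d)
  w <- seq(40, 120, 10)
  expect_true(all(diff(bmr(w, "30-34", "female")) > 0))
  expect_error(bmr(-5, "30-34", "male"), "negative")
})

test_that("PAL interpolates between sedentary and active multipliers", {
  pp <- default_parameters()$pal
  # p = 0: fully active
  pp0 <- pp; pp0$curve$base <- 0; pp0$curve$delta <- 0
  expect_equal(pal(1e4, "15-59", "male", pp0), pp$active)
  # p = 1: fully sedentary
  pp1 <- pp; pp1$curve$base <- 1; pp1$curve$delta <- 0
  expect_equal(pal(1e4, "15-59", "male", pp1), pp$sedentary)
  # non-increasing in income when inactivity rises with income
  y <- seq(0, 1e5, length.out = 50)
  expect_true(all(diff(pal(y, "60+", "female", pp)) <= 0))
  # children income-flat by default
  expect_equal(pal(0, "0-14", "male", pp), pal(1e5, "0-14", "male", pp))
  expect_true(all(pal(y, "15-59", "male", pp) >= 1.2 &
                    pal(y, "15-59", "male", pp) <= 2.5))
})

test_that("per-class intake is BMR times PAL", {
  b <- bmr(70, "30-34", "male")
  expect_equal(intake_per_class(70, 1.76, "30-34", "male"), b * 1.76)
  expect_equal(round(intake_per_class(70, 1.76, "30-34", "male")), 2950)
  expect_equal(intake_per_class(70, 1, "30-34", "male"), b)
  # lower representative BMI => lower weight => lower intake
  h <- 170
  w_low <- body_weight(17.5, h); w_norm <- body_weight(22.5, h)
  expect_lt(intake_per_class(w_low, 1.6, "30-34", "male"),
            intake_per_class(w_norm, 1.6, "30-34", "male"))
})

test_that("aggregate intake is a share- and population-weighted mean plus pregnancy", {
  one <- function(intake, pop, age = "30-34") {
    list(
      intake = tibble::tibble(country = "A", age = age, sex = "male",
                              bmi_class = "20-25", intake_kcal = intake),
      shares = tibble::tibble(country = "A", age_group = cohort_age_group(age),
                              sex = "male", bmi_class = "20-25", share = 1),
      pop = tibble::tibble(country = "A", age = age, sex = "male",
                           population = pop))
  }
  f <- one(2000, 100)
  out <- aggregate_intake(f$intake, f$shares, f$pop, pregnancy_kcal = 0)
  expect_equal(out$intake_kcal, 2000)

  # two equally sized cohorts at 1800 and 2200
  intake <- tibble::tibble(country = "A", age = c("30-34", "35-39"), sex = "male",
                           bmi_class = "20-25", intake_kcal = c(1800, 2200))
  shares <- tibble::tibble(country = "A", age_group = "15-59", sex = "male",
                           bmi_class = "20-25", share = 1)
  pop <- tibble::tibble(country = "A", age = c("30-34", "35-39"), sex = "male",
                        population = c(50, 50))
  expect_equal(aggregate_intake(intake, shares, pop, 0)$intake_kcal, 2000)

  # pregnancy add-on: newborn cohort at 10% of the population adds N*0.1/5
  intake2 <- dplyr::bind_rows(
    intake,
    tibble::tibble(country = "A", age = "0-4", sex = "male",
                   bmi_class = "-1-1sd", intake_kcal = 1000))
  shares2 <- dplyr::bind_rows(
    shares,
    tibble::tibble(country = "A", age_group = "0-14", sex = "male",
                   bmi_class = "-1-1sd", share = 1))
  pop2 <- dplyr::bind_rows(
    dplyr::mutate(pop, population = c(45, 45)),
    tibble::tibble(country = "A", age = "0-4", sex = "male", population = 10))
  base <- aggregate_intake(intake2, shares2, pop2, pregnancy_kcal = 0)$intake_kcal
  with_n <- aggregate_intake(intake2, shares2, pop2, pregnancy_kcal = 460)$intake_kcal
  expect_equal(with_n - base, 460 * 0.1 / 5)

  expect_error(aggregate_intake(f$intake, f$shares,
                                dplyr::mutate(f$pop, population = 0), 0),
               "zero total population")
})

test_that("aggregate intake respects weighted-mean bounds and share monotonicity", {
  set.seed(5)
  for (r in 1:10) {
    intakes <- stats::runif(3, 1500, 3000)
    sh <- stats::runif(3); sh <- sh / sum(sh)
    intake <- tibble::tibble(country = "A", age = "30-34", sex = "male",
                             bmi_class = c("<18.5", "20-25", "30-35"),
                             intake_kcal = sort(intakes))
    shares <- tibble::tibble(country = "A", age_group = "15-59", sex = "male",
                             bmi_class = c("<18.5", "20-25", "30-35"), share = sh)
    pop <- tibble::tibble(country = "A", age = "30-34", sex = "male",
                          population = 1000)
    out <- aggregate_intake(intake, shares, pop, 0)$intake_kcal
    expect_gte(out, min(intakes)); expect_lte(out, max(intakes))
    # moving share mass from the lowest to the highest class raises intake
    sh2 <- sh + c(-sh[1], 0, sh[1])
    out2 <- aggregate_intake(intake, dplyr::mutate(shares, share = sh2), pop,
                             0)$intake_kcal
    expect_gte(out2, out)
  }
})

test_that("underweight versus normal-weight intake differs by a small fraction", {
  # all-underweight vs all-normal populations: the intake gap is well below
  # 10% of total intake, mirroring why eliminating underweight barely
  # raises demand
  h <- 165
  base <- default_parameters()
  w_u <- body_weight(17.5, h); w_n <- body_weight(22.5, h)
  i_u <- intake_per_class(w_u, 1.7, "30-34", "female")
  i_n <- intake_per_class(w_n, 1.7, "30-34", "female")
  expect_lt((i_n - i_u) / i_n, 0.10)
  expect_gt(i_n, i_u)
})
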
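make_height_fixture <- function(alpha = c(95, 90), beta = c(0.06, 0.055)) {
  years <- seq(1965, 2010, 5)
  countries <- sprintf("H%02d", 1:6)
  g <- tidyr::expand_grid(country = countries, year = years) |>
    dplyr::mutate(g_kcal = 200 + 40 * (match(country, countries) - 1) +
                    3 * (year - 1965))
  gm <- trailing_g(g, require_full = TRUE)
  h <- dplyr::bind_rows(lapply(seq_along(sexes()), function(s) {
    gm |> dplyr::mutate(age = "15-19", sex = sexes()[s],
                        height_cm = alpha[s] * g_mean^beta[s]) |>
      dplyr::select(country, year, age, sex, height_cm)
  }))
  list(heights = h, g = g)
}

test_that("height regression recovers a noiseless power law (closed-form OLS oracle)", {
  fx <- make_height_fixture()
  fit <- fit_height_regression(fx$heights, fx$g)
  expect_equal(fit$alpha, c(95, 90), tolerance = 1e-6)
  expect_equal(fit$beta, c(0.06, 0.055), tolerance = 1e-6)

  # independent closed-form check for one sex: beta = cov/var of logs
  d <- dplyr::inner_join(
    dplyr::filter(fx$heights, sex == "male"),
    trailing_g(fx$g, require_full = TRUE), by = c("country", "year"))
  beta_hat <- stats::cov(log(d$g_mean), log(d$height_cm)) / stats::var(log(d$g_mean))
  alpha_hat <- exp(mean(log(d$height_cm)) - beta_hat * mean(log(d$g_mean)))
  expect_equal(fit$beta[fit$sex == "male"], beta_hat, tolerance = 1e-10)
  expect_equal(fit$alpha[fit$sex == "male"], alpha_hat, tolerance = 1e-10)
})

test_that("height regression degenerate and flat cases behave", {
  fx <- make_height_fixture()
  flat_g <- fx$g |> dplyr::mutate(g_kcal = 600)
  flat_h <- fx$heights |> dplyr::mutate(height_cm = 170)
  expect_error(fit_height_regression(flat_h, flat_g), "degenerate")

  const_h <- fx$heights |> dplyr::mutate(height_cm = 170)
  fit <- fit_height_regression(const_h, fx$g)
  expect_equal(fit$beta, c(0, 0), tolerance = 1e-10)
  expect_equal(fit$alpha, c(170, 170), tolerance = 1e-8)

  neg <- fx$heights
  neg$height_cm[1] <- -1
  expect_error(fit_height_regression(neg, fx$g), "positive")
})

test_that("child heights scale with the young-adult divergence from the standard", {
  params <- tibble::tibble(sex = sexes(), alpha = c(170, 158), beta = 0)
  std <- growth_standard()
  h <- project_height(params, c(X1 = 1000), year = 1970)
  ratio <- 170 / std$height_cm[std$sex == "male" & std$age == 18]
  for (coh in c("0-4", "5-9", "10-14")) {
    midage <- cohort_midpoints()[[coh]]
    ref <- stats::approx(std$age[std$sex == "male"],
                         std$height_cm[std$sex == "male"], xout = midage)$y
    got <- h$height_cm[h$age == coh & h$sex == "male"]
    expect_equal(got, ref * ratio, tolerance = 1e-12)
  }
  # hand instance of the same rule at the standard's tabulated age 10
  expect_equal(137.8 * 170 / 176.5, 132.7, tolerance = 1e-3)
  # children grow with age within a timestep
  kid <- h[h$sex == "male" & h$age %in% c("0-4", "5-9", "10-14", "15-19"), ]
  expect_true(all(diff(kid$height_cm[match(c("0-4", "5-9", "10-14", "15-19"),
                                           kid$age)]) > 0))
})

test_that("adult cohorts carry their height forward one class per step", {
  params <- tibble::tibble(sex = sexes(), alpha = c(170, 158), beta = 0)
  h0 <- project_height(params, c(A = 500, B = 900), year = 1965)
  h0$height_cm[h0$age == "15-19" & h0$sex == "male" & h0$country == "A"] <- 170
  params2 <- tibble::tibble(sex = sexes(), alpha = c(171, 159), beta = 0)
  h1 <- project_height(params2, c(A = 600, B = 950), previous = h0, year = 1970)
  expect_equal(h1$height_cm[h1$age == "20-24" & h1$sex == "male" & h1$country == "A"],
               170)
  # 100+ absorbs the incoming 95-99 cohort
  expect_equal(h1$height_cm[h1$age == "100+" & h1$sex == "female" & h1$country == "B"],
               h0$height_cm[h0$age == "95-99" & h0$sex == "female" & h0$country == "B"])
  # monotone in the diet-quality driver for beta >= 0
  pp <- tibble::tibble(sex = sexes(), alpha = c(115, 108), beta = c(0.06, 0.055))
  lo <- project_height(pp, c(A = 500), year = 1965)
  hi <- project_height(pp, c(A = 2000), year = 1965)
  expect_true(all(hi$height_cm >= lo$height_cm))
})

test_that("body weight follows W = B (H/100)^2", {
  expect_equal(body_weight(22.5, 160), 57.6)
  expect_equal(body_weight(22.5, 157), 55.46025)
  expect_equal(body_weight(22.5, 0), 0)
  expect_error(body_weight(22.5, -1), "negative")
})

test_that("BMI share curves are recovered from noiseless panels", {
  truth <- default_parameters()$bmi
  years <- seq(1965, 2050, 5)
  countries <- sprintf("B%02d", 1:8)
  income <- tidyr::expand_grid(country = countries, year = years) |>
    dplyr::mutate(income = 500 * exp(0.5 * (match(country, countries) - 1)) +
                    20 * (year - 1965))
  shares <- income |>
    dplyr::cross_join(dplyr::distinct(truth, age_group, sex, bmi_class)) |>
    dplyr::left_join(truth, by = c("age_group", "sex", "bmi_class")) |>
    dplyr::mutate(share = base + delta * income / (halfsat + income)) |>
    dplyr::select(country, year, age_group, sex, bmi_class, share)
  fit <- fit_bmi_shares(shares, income)
  key <- function(x) paste(x$age_group, x$sex, x$bmi_class)
  m <- match(key(truth), key(fit))
  expect_lt(max(abs(fit$base[m] - truth$base) / pmax(truth$base, 1e-12)), 1e-4)
  expect_lt(max(abs(fit$delta[m] - truth$delta) / abs(truth$delta)), 1e-4)
  expect_lt(max(abs(fit$halfsat[m] - truth$halfsat) / truth$halfsat), 1e-4)
  # fitted adult obesity curves rise with income
  ob <- fit[fit$age_group == "15-59" & fit$bmi_class %in% c("30-35", "35+"), ]
  expect_true(all(ob$delta > 0))
})

test_that("flat share panels collapse to a constant curve", {
  years <- seq(1965, 2000, 5)
  income <- tidyr::expand_grid(country = c("F1", "F2"), year = years) |>
    dplyr::mutate(income = 1000 + 500 * (year - 1965) / 5)
  shares <- income |>
    dplyr::cross_join(tibble::tibble(bmi_class = c("a", "b"),
                                     value = c(0.25, 0.75))) |>
    dplyr::mutate(age_group = "15-59", sex = "male", share = value) |>
    dplyr::select(country, year, age_group, sex, bmi_class, share)
  fit <- fit_bmi_shares(shares, income)
  expect_equal(fit$base + ifelse(is.na(fit$halfsat), 0, fit$delta / 2) * 0,
               c(0.25, 0.75), tolerance = 1e-8)
  expect_equal(fit$delta, c(0, 0), tolerance = 1e-8)
})

test_that("predicted shares form a proper distribution at any income", {
  p <- default_parameters()$bmi
  set.seed(1)
  for (y in c(0, stats::runif(20, 0, 2e5))) {
    for (ag in age_groups()) {
      s <- predict_bmi_shares(p, y, ag, "female")
      expect_lt(abs(sum(s$share) - 1), 1e-12)
      expect_true(all(s$share >= 0))
    }
  }
  expect_error(predict_bmi_shares(p, -5, "15-59", "male"), "negative")
})

test_that("share curves hit baseline at zero and half-saturation at Y = k", {
  p <- tibble::tibble(age_group = "15-59", sex = "male",
                      bmi_class = c("lo", "hi"),
                      base = c(1, 0), delta = c(-0.4, 0.4), halfsat = 5000)
  at0 <- predict_bmi_shares(p, 0, "15-59", "male")
  expect_equal(at0$share, c(1, 0))
  athalf <- predict_bmi_shares(p, 5000, "15-59", "male")
  # raw shares sum to 1 here, so renormalization is the identity and the
  # rising class sits at exactly half its saturation delta
  expect_equal(athalf$share[athalf$bmi_class == "hi"], 0.2)
})
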
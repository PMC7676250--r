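# Shared fixtures, built once per test run. Worlds are generated in code
# (no stored data); the noiseless world doubles as the model-true oracle
# for recovery and cross-validation checks.

.fixture_env <- new.env(parent = emptyenv())

.fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

world_noiseless_small <- function() {
  .fixture("small", function() {
    make_world(world_spec(n_countries = 8, seed = 42,
                          noise = list(calorie = 0, share_logit = 0, height = 0)))
  })
}

world_noiseless_30 <- function() {
  .fixture("w30", function() {
    make_world(world_spec(n_countries = 30, seed = 7,
                          noise = list(calorie = 0, share_logit = 0, height = 0)))
  })
}

world_noisy_default <- function() {
  .fixture("w30noisy", function() make_world(world_spec(n_countries = 30, seed = 7)))
}

baseline_of <- function(world) attr(world$observations, "baseline")

# constant-driver world: identical income and population at every timestep
constant_drivers <- function(n = 3, years = seq(1965, 2030, 5), income = 4000,
                             pop_growth = 1) {
  countries <- sprintf("K%02d", seq_len(n))
  cohorts <- age_cohorts()
  pyramid <- exp(-0.03 * cohort_midpoints())
  inc <- tidyr::expand_grid(country = countries, year = years) |>
    dplyr::mutate(income = income)
  pop <- tidyr::expand_grid(country = countries, year = years,
                            age = cohorts, sex = sexes()) |>
    dplyr::mutate(population = 1e6 * pyramid[age] *
                    pop_growth^((year - min(years)) / 5))
  structure(list(income = inc, population = pop), class = "ns_drivers")
}
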
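test_that("generators are deterministic given the seed", {
  spec <- simulation_spec(seed = 7)
  expect_identical(simulate_incidence_table(spec),
                   simulate_incidence_table(spec))
  d1 <- simulate_km_dataset(weibull_params(1.4, 9), 200, 0.05, 10, seed = 3)
  d2 <- simulate_km_dataset(weibull_params(1.4, 9), 200, 0.05, 10, seed = 3)
  expect_identical(d1, d2)
  expect_false(identical(
    d1, simulate_km_dataset(weibull_params(1.4, 9), 200, 0.05, 10, seed = 4)))
})

test_that("incidence counts follow the Poisson law of the rate model", {
  # flat slopes: every cell has mean population * rate
  spec <- simulation_spec(seed = 11, rate_age_slope = 0, rate_year_slope = 0,
                          baseline_rate = 100, base_population = 1e5,
                          population_growth = 0)
  tab <- simulate_incidence_table(spec)
  # base_population decays over bands in the pyramid; check cell-wise mean
  mu <- tab$population * 100 / 1e5
  z <- (sum(tab$cases) - sum(mu)) / sqrt(sum(mu))
  expect_lt(abs(z), 4)

  # dispersion index of pooled draws within 3 s.e. of 1
  set.seed(42)
  draws <- rpois(10000, 100)
  ratio <- var(draws) / mean(draws)
  expect_lt(abs(ratio - 1), 3 * sqrt(2 / (length(draws) - 1)))

  # zero population gives zero counts
  spec0 <- simulation_spec(seed = 1, base_population = 1)
  tab0 <- simulate_incidence_table(spec0)
  expect_true(all(tab0$cases[tab0$population == 0] == 0))

  # extreme slopes are rejected with a diagnostic
  expect_error(simulate_incidence_table(
    simulation_spec(rate_age_slope = 1e5)), "non-finite")
})

test_that("simulated event data match the generating distribution", {
  # shape 1 is exponential with mean = scale
  d <- simulate_km_dataset(weibull_params(1, 10), 20000, 0, Inf, seed = 5)
  expect_true(all(d$event))
  expect_lt(abs(mean(d$time) - 10), 3 * 10 / sqrt(20000))

  # cutoff 0 censors everyone at 0
  d0 <- simulate_km_dataset(weibull_params(1.5, 8), 50, 0, 0, seed = 1)
  expect_true(all(d0$time == 0))
  expect_true(all(!d0$event))

  # KM at t = scale recovers exp(-1) within 3 s.e.
  d2 <- simulate_km_dataset(weibull_params(1.5, 8), 5000, 0, Inf, seed = 9)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(d2))
  s <- summary(fit, times = 8)
  expect_lt(abs(s$surv - exp(-1)), 3 * s$std.err)
})

test_that("life table is a proper, closed mortality schedule", {
  lt <- make_life_table(max_age = 110, gompertz = c(1e-5, 0.1))
  expect_true(all(lt$qx > 0 & lt$qx <= 1))
  expect_true(all(diff(lt$qx) > 0))
  expect_equal(lt$qx[nrow(lt)], 1)

  # hand-computed 1 - exp(-h(a)) at three ages
  for (a in c(40, 70, 95))
    expect_equal(lt$qx[lt$age == a], 1 - exp(-1e-5 * exp(0.1 * a)))

  # b = 0 gives a constant hazard, hence identical qx below the closure age
  flat <- make_life_table(max_age = 50, gompertz = c(0.05, 0))
  expect_equal(length(unique(flat$qx[-nrow(flat)])), 1L)
})

test_that("default config carries the base-case constants", {
  cfg <- make_default_config()
  expect_equal(cfg$discount_rate, 0.03)
  expect_equal(cfg$dcis_frac, 0.18)
  expect_equal(cfg$metastatic_frac, 0.07)
  expect_equal(cfg$recurrence_cost, 183170)
  expect_equal(cfg$horizon_year, 2035)
  expect_equal(cfg$reference_year, 2017)
  expect_equal(cfg$mean_weight_kg, 66.4)
  expect_equal(cfg$body_surface_m2, 1.73)
  expect_equal(mean_followup(cfg$cohort_years, cfg$horizon_year), 23.5)
})

test_that("synthetic inputs round-trip through CSV files", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(seed = 2, km_n = 50)
  files <- write_synthetic_inputs(spec, dir)
  expect_true(all(file.exists(files)))
  inc <- read.csv(file.path(dir, "incidence.csv"))
  expect_identical(nrow(inc), nrow(simulate_incidence_table(spec)))
  km <- read.csv(file.path(dir, "km_os_tct.csv"))
  expect_true(all(c("time", "survival", "n_risk") %in% names(km)))
  expect_true(all(diff(km$survival) <= 0))
})

test_that("config serializes to a structured text file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(make_default_config(), path)
  back <- yaml::read_yaml(path)
  expect_equal(back$discount_rate, 0.03)
  expect_equal(back$recurrence_cost, 183170)
  expect_equal(back$prices$drug[1], "trastuzumab_iv")
})
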
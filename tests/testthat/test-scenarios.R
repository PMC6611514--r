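cfg <- make_default_config()

test_that("market-share series validates its invariants", {
  expect_error(market_share_series(2014, 0.9, 0.5), "2015")
  expect_error(market_share_series(2016, 1.2, 0), "\\[0, 1\\]")
  ms <- default_market_shares()
  expect_equal(ms$share[ms$year == 2006], 0.40)
  expect_true(all(ms$share[ms$year >= 2014] == 1))
  expect_true(all(ms$sc_share[ms$year < 2015] == 0))
})

test_that("degenerate market shares collapse to the pure scenarios", {
  inputs <- make_model_inputs(2010:2011)
  curves <- prepare_efficacy_curves(inputs$km, cfg, inputs$life_table,
                                    inputs$age_weights)
  none <- market_share_series(2006:2017, 0)
  all_t <- market_share_series(2006:2017, 1)

  rw0 <- run_scenario(inputs$cohorts, curves, none, cfg, "real_world")
  ct <- run_scenario(inputs$cohorts, curves, none, cfg, "ct_only")
  expect_equal(rw0$total_ly, ct$total_ly)
  expect_equal(rw0$total_cost, ct$total_cost)

  rw1 <- run_scenario(inputs$cohorts, curves, all_t, cfg, "real_world")
  fu <- run_scenario(inputs$cohorts, curves, all_t, cfg, "full_use")
  expect_equal(rw1$total_ly, fu$total_ly)
  expect_equal(rw1$total_cost, fu$total_cost)
})

test_that("real-world results are convex combinations of pure scenarios", {
  inputs <- make_model_inputs(2010)
  curves <- prepare_efficacy_curves(inputs$km, cfg, inputs$life_table,
                                    inputs$age_weights)
  half <- market_share_series(2006:2017, 0.5)
  rw <- run_scenario(inputs$cohorts, curves, half, cfg, "real_world")
  fu <- run_scenario(inputs$cohorts, curves, half, cfg, "full_use")
  ct <- run_scenario(inputs$cohorts, curves, half, cfg, "ct_only")
  expect_equal(rw$total_ly, 0.5 * fu$total_ly + 0.5 * ct$total_ly,
               tolerance = 1e-9)
  expect_equal(rw$total_dfly, 0.5 * fu$total_dfly + 0.5 * ct$total_dfly,
               tolerance = 1e-9)
  expect_equal(rw$total_cost, 0.5 * fu$total_cost + 0.5 * ct$total_cost,
               tolerance = 1e-9)
})

test_that("ICER arithmetic reproduces the published cost-effect table", {
  a <- scenario_result(616354, 534907, total_cost = 1581553536)
  b <- scenario_result(564137, 489916, total_cost = 503587698)
  icer <- compute_icer(a, b)
  expect_equal(icer$inc_ly, 52217)
  expect_equal(icer$inc_dfly, 44991)
  expect_equal(icer$icer_ly_eur, 20644)
  expect_equal(icer$icer_dfly_eur, 23960)
  expect_false(icer$dominance)

  # identical scenarios flag dominance instead of dividing by zero
  same <- compute_icer(a, a)
  expect_true(same$dominance)
  expect_true(is.na(same$icer_ly))
})

test_that("sensitivity battery runs and orders as expected", {
  inputs <- make_model_inputs(2010:2012)
  sa <- suppressWarnings(run_sensitivity(inputs, cfg))
  get <- function(nm, col) sa[sa$scenario == nm, col]
  base <- get("base_case", "lyg")

  # LYG strictly decreasing in the discount rate
  expect_gt(get("discount_0", "lyg"), base)
  expect_gt(base, get("discount_5", "lyg"))
  # shorter horizon cannot gain more life years
  expect_lte(get("horizon_2030", "lyg"), base)
  # pure cost overrides leave effects untouched, move costs only
  expect_equal(get("recurrence_cost_low", "lyg"), base)
  expect_equal(get("recurrence_cost_high", "lyg"), base)
  expect_false(get("recurrence_cost_low", "inc_cost") ==
                 get("recurrence_cost_high", "inc_cost"))
  # chemotherapy cost has no effect on incremental outcomes at all
  expect_equal(get("ct_cost_minus25", "inc_cost"),
               get("base_case", "inc_cost"), tolerance = 1e-6)

  # the alternative-efficacy slot is skipped when no curves are supplied
  expect_false("efficacy_alternative" %in% sa$scenario)
  expect_warning(run_sensitivity(inputs, cfg,
    scenarios = list(alt = list(efficacy = "alternative"))), "skipped")

  # undeclared knobs are refused
  expect_error(run_sensitivity(inputs, cfg,
    scenarios = list(bad = list(her2_prevalence = 1))), "undeclared")
})

test_that("alternative efficacy curves flow through the SA slot", {
  inputs <- make_model_inputs(2010:2011)
  alt <- exact_km_inputs()
  # a weaker treated arm as the alternative source
  alt$os_tct$params <- weibull_params(1.3, 33)
  alt$os_tct$km <- survival_at(alt$os_tct$params, 0:10)
  alt$dfs_tct$params <- weibull_params(1.1, 24)
  alt$dfs_tct$km <- survival_at(alt$dfs_tct$params, 0:10)
  inputs$alt_efficacy <- list(alternative = alt)
  sa <- run_sensitivity(inputs, cfg,
                        scenarios = list(alt = list(efficacy = "alternative")))
  expect_true("alt" %in% sa$scenario)
  expect_lt(sa$lyg[sa$scenario == "alt"],
            sa$lyg[sa$scenario == "base_case"])
})

test_that("full model run reports increments, ICER and comparator", {
  inputs <- make_model_inputs(2010:2012)
  run <- run_full_model(inputs, cfg)
  expect_gt(run$increment$inc_ly, 0)
  expect_gt(run$increment$inc_dfly, 0)
  expect_gt(run$icer$icer_ly, 0)
  # full-use gains at least the real-world gains (share <= 1)
  expect_gte(run$icer$inc_ly, run$increment$inc_ly)
  # the general population outlives both disease scenarios
  expect_gt(run$general_population_ly, run$full_use$total_ly)
})
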
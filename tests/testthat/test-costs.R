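cfg <- make_default_config()

test_that("dosing schedules follow the posologies", {
  # IV trastuzumab: 18 administrations, 8 mg/kg loading then 6 mg/kg q3w
  d <- doses_in_first_year(regimen_trastuzumab_iv())
  expect_equal(nrow(d), 18)
  expect_equal(d$week, seq(0, 51, by = 3))
  expect_equal(d$mg[1], 8 * 66.4)       # 531.2 mg loading
  expect_true(all(d$mg[-1] == 6 * 66.4))

  # SC trastuzumab: 18 flat 600 mg administrations
  dsc <- doses_in_first_year(regimen_trastuzumab_sc())
  expect_equal(nrow(dsc), 18)
  expect_true(all(dsc$mg == 600))
  expect_true(all(dsc$route == "SC"))

  # weekly paclitaxel x 12 at 80 mg/m2
  dact <- doses_in_first_year(regimen_act("paclitaxel"))
  pac <- dact[dact$drug == "paclitaxel", ]
  expect_equal(nrow(pac), 12)
  expect_true(all(pac$mg == 80 * 1.73))  # 138.4 mg
  expect_equal(nrow(dact[dact$drug == "doxorubicin", ]), 4)
  expect_equal(nrow(dact[dact$drug == "cyclophosphamide", ]), 6)
})

test_that("vial policies price administrations correctly", {
  prices <- data.frame(drug = "trastuzumab_iv", vial_mg = 150, price = 100)
  one <- data.frame(week = 0, drug = "trastuzumab_iv", mg = 531.2,
                    route = "IV")
  # 531.2 mg in 150 mg vials: 4 whole vials
  expect_equal(as.numeric(drug_cost(one, prices, "whole_vials")), 400)
  expect_equal(as.numeric(drug_cost(one, prices, "exact_mg")),
               531.2 / 150 * 100)
  # empty dose list costs nothing
  expect_equal(as.numeric(drug_cost(one[0, ], prices)), 0)
  # unpriced drug is reported by name
  bad <- data.frame(week = 0, drug = "pertuzumab", mg = 420, route = "IV")
  expect_error(drug_cost(bad, prices), "pertuzumab")
})

test_that("statutory deduction schedule by year and formulation", {
  expect_equal(apply_deduction(100, 2008, "IV"), 100)
  expect_equal(apply_deduction(100, 2012, "IV"), 92.5)
  expect_equal(apply_deduction(100, 2016, "IV"), 85)
  expect_equal(apply_deduction(100, 2016, "SC"), 92.5)
  # monotone: later-year cost never exceeds earlier-year cost
  iv <- vapply(2006:2017, function(y) apply_deduction(100, y, "IV"),
               numeric(1))
  expect_true(all(diff(iv) <= 0))
})

test_that("ancillary cost stream prices visits, echos and recurrences", {
  cfg1 <- cfg
  cfg1$cpi$index <- 1          # neutral CPI
  cfg1$discount_rate <- 0
  flat <- survival_curve(rep(1, 11), endpoint = "OS")
  tr <- build_cohort_trace(1, flat, flat, 2010, 2020)

  cs <- ancillary_costs(tr, NULL, cfg1, treated_with_T = 0,
                        n_iv_visits = 10)
  admin <- cs[cs$category == "administration", ]
  expect_equal(sum(admin$cost), 10 * 211.64)    # 2,116.40 in the cohort year
  expect_equal(admin$cost[admin$calendar_year == 2010], 2116.4)
  # untreated patients accrue no echo monitoring
  expect_equal(sum(cs$cost[cs$category == "monitoring"]), 0)
  # flat curves produce no progressions, hence no recurrence cost
  expect_equal(sum(cs$cost[cs$category == "recurrence"]), 0)

  # treated: 4 echos in the treatment year + 1/year disease-free after
  cs_t <- ancillary_costs(tr, NULL, cfg1, treated_with_T = 1,
                          n_iv_visits = 10)
  mon <- cs_t[cs_t$category == "monitoring", ]
  expect_equal(mon$cost[mon$calendar_year == 2010], 4 * 133)
  expect_equal(mon$cost[mon$calendar_year == 2015], 1 * 133)

  # a single progression incurs the one-off cost in its year only
  os <- survival_curve(c(1, 1, rep(0.99, 9)), endpoint = "OS")
  dfs <- survival_curve(c(1, 0.99, rep(0.98, 9)), endpoint = "DFS")
  tr2 <- build_cohort_trace(100, os, dfs, 2010, 2020,
                            progression_method = "Markov")
  cs2 <- ancillary_costs(tr2, NULL, cfg1, treated_with_T = 0,
                         n_iv_visits = 0)
  rec <- cs2[cs2$category == "recurrence", ]
  expect_equal(rec$cost[rec$calendar_year == 2010], 1 * 183170)
  expect_equal(sum(rec$cost[rec$calendar_year != 2010]), 0)
})

test_that("trastuzumab cost falls with the deduction schedule", {
  c2008 <- trastuzumab_cost(cfg, 2008, "IV")
  c2012 <- trastuzumab_cost(cfg, 2012, "IV")
  c2016 <- trastuzumab_cost(cfg, 2016, "IV")
  expect_gt(c2008, c2012)
  expect_gt(c2012, c2016)
  expect_equal(c2012 / c2008, 0.925)
  expect_equal(c2016 / c2008, 0.85)
})

test_that("co-administered IV drugs share day-hospital visits", {
  # AC-T alone: 6 AC weeks + 12 weekly taxane weeks
  expect_equal(iv_visits(regimen_act("paclitaxel")), 18)
  expect_equal(iv_visits(regimen_tc("docetaxel")), 4)
  # adding IV trastuzumab only adds the non-overlapping q3w weeks
  both <- iv_visits(list(regimen_act("paclitaxel"),
                         regimen_trastuzumab_iv()))
  expect_lt(both, 18 + 18)
  expect_equal(both, 26)
})

test_that("chemotherapy backbone cancels out of incremental costs", {
  inputs <- make_model_inputs(2010:2012)
  run_with_mult <- function(m) {
    cfg2 <- cfg
    cfg2$ct_cost_multiplier <- m
    run_full_model(inputs, cfg2)
  }
  r1 <- run_with_mult(1)
  r2 <- run_with_mult(1.25)
  # absolute scenario costs move, increments do not
  expect_gt(r2$full_use$total_cost, r1$full_use$total_cost)
  expect_equal(r2$icer$inc_cost, r1$icer$inc_cost, tolerance = 1e-6)
  expect_equal(r2$increment$inc_ly, r1$increment$inc_ly)
})

test_that("trastuzumab reduces the recurrence-category cost", {
  inputs <- make_model_inputs(2010:2012)
  run <- run_full_model(inputs, cfg)
  rec_diff <- run$full_use$cost_by_category[["recurrence"]] -
    run$ct_only$cost_by_category[["recurrence"]]
  expect_lt(rec_diff, 0)
})
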
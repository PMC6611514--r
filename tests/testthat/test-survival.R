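test_that("Weibull survival has its closed forms", {
  expect_equal(survival_at(weibull_params(2.3, 7), 0), 1)
  expect_equal(survival_at(weibull_params(1, 10), 10), exp(-1))
  expect_equal(survival_at(weibull_params(2, 10), 5), exp(-0.25))
  expect_error(survival_at(weibull_params(1, 1), -1), ">= 0")
  expect_error(weibull_params(0, 1))
  expect_error(weibull_params(1, -2))
})

test_that("censored log-likelihood matches a direct summation oracle", {
  set.seed(31)
  for (rep in 1:5) {
    d <- simulate_km_dataset(weibull_params(1.3, 6), 20, 0.1, 8,
                             seed = 100 + rep)
    fit <- fit_weibull_mle(d)
    k <- fit$shape; lam <- fit$scale
    # independent oracle via the distribution functions
    oracle <- sum(ifelse(d$event,
                         log(stats::dweibull(d$time, k, lam)),
                         stats::pweibull(d$time, k, lam, lower.tail = FALSE,
                                         log.p = TRUE)))
    expect_equal(attr(fit, "loglik"), oracle, tolerance = 1e-8)
  }
})

test_that("fixed-shape MLE reduces to the exponential closed form", {
  d <- event_data(c(2, 5, 1, 7, 3), rep(TRUE, 5))
  fit <- fit_weibull_mle(d, shape = 1)
  expect_equal(fit$scale, sum(d$time) / 5)
})

test_that("MLE recovers generating parameters and beats a local grid", {
  d <- simulate_km_dataset(weibull_params(1.4, 9), 2000, 0.05, Inf,
                           seed = 17)
  fit <- fit_weibull_mle(d)
  se <- attr(fit, "se")
  expect_lt(abs(fit$shape - 1.4), 3 * se[["shape"]])
  expect_lt(abs(fit$scale - 9), 3 * se[["scale"]])

  # optimum dominates a 21-point grid around it
  grid <- expand.grid(k = fit$shape * seq(0.9, 1.1, length.out = 21),
                      keep = 1)
  ll_at <- function(k, lam) sum(ifelse(
    d$event, log(stats::dweibull(d$time, k, lam)),
    stats::pweibull(d$time, k, lam, lower.tail = FALSE, log.p = TRUE)))
  ll_opt <- ll_at(fit$shape, fit$scale)
  for (k in grid$k) expect_lte(ll_at(k, fit$scale), ll_opt + 1e-9)

  # independent cross-check against survreg's Weibull AFT fit
  sr <- survival::survreg(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(d), dist = "weibull")
  expect_equal(fit$shape, 1 / sr$scale, tolerance = 1e-3)
  expect_equal(fit$scale, exp(unname(coef(sr))), tolerance = 1e-3)
})

test_that("pseudo-IPD reconstruction inverts the KM estimator", {
  # complete (uncensored) sample: the digitized empirical curve returns
  # the exact event times
  times <- c(0.5, 1, 1.5, 2, 3, 4, 5.5, 6, 8, 9)
  surv <- 1 - seq_along(times) / 10
  ipd <- reconstruct_pseudo_ipd(
    data.frame(time = c(0, times), survival = c(1, surv)), n_total = 10)
  expect_equal(sort(ipd$time[ipd$event]), times)
  expect_equal(sum(ipd$event), 10)

  # flat curve: everyone censored at the cutoff
  flat <- reconstruct_pseudo_ipd(
    data.frame(time = c(0, 5), survival = c(1, 1)), n_total = 100)
  expect_equal(nrow(flat), 100)
  expect_true(all(!flat$event))
  expect_true(all(flat$time == 5))

  # increasing survival is rejected
  expect_error(reconstruct_pseudo_ipd(
    data.frame(time = c(0, 1, 2), survival = c(1, 0.8, 0.9)), 50),
    "non-increasing")
})

test_that("digitize -> reconstruct round-trip reproduces the KM curve", {
  d <- simulate_km_dataset(weibull_params(1.2, 12), 300, 0.05, 10,
                           seed = 23)
  dig <- digitize_km(d)
  ipd <- reconstruct_pseudo_ipd(dig, n_total = 300)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ipd))
  back <- summary(fit, times = dig$time, extend = TRUE)$surv
  expect_lt(max(abs(back - dig$survival)), 0.01)
})

test_that("stitching is continuous and degenerates correctly", {
  p <- weibull_params(1.3, 20)
  # switch at 0: pure parametric
  c0 <- stitch_curve(numeric(0), p, 0, 15)
  expect_equal(c0$values, survival_at(p, 0:15))

  # km equal to the parametric curve: stitched = parametric everywhere
  km <- survival_at(p, 0:10)
  c1 <- stitch_curve(km, p, 10, 25)
  expect_equal(c1$values, survival_at(p, 0:25), tolerance = 1e-12)

  # continuity at the switch with a km that disagrees with the tail
  km2 <- km * c(1, rep(0.98, 10))
  km2[1] <- 1
  c2 <- stitch_curve(km2, p, 10, 25, endpoint = "DFS")
  expect_equal(c2$values[11], km2[11])
  expect_true(all(diff(c2$values) <= 1e-12))
})

test_that("background-mortality adjustment applies the hazard-max rule", {
  aw <- data.frame(age = 60, weight = 1)
  # negligible background mortality leaves the curve unchanged
  lt0 <- make_life_table(max_age = 120, gompertz = c(1e-12, 0))
  cur <- survival_curve(survival_at(weibull_params(1.3, 20), 0:20),
                        endpoint = "OS")
  adj <- adjust_for_background_mortality(cur, lt0, aw)
  expect_equal(adj$values, cur$values, tolerance = 1e-9)

  # flat disease curve + constant q = 0.1 gives 0.9^t
  flat <- survival_curve(rep(1, 11), endpoint = "OS")
  lt <- make_life_table(max_age = 120, gompertz = c(-log(0.9), 0))
  adj2 <- adjust_for_background_mortality(flat, lt, aw)
  expect_equal(adj2$values, 0.9^(0:10), tolerance = 1e-12)

  # property: adjusted <= unadjusted, and equals a brute-force
  # year-by-year recomputation
  lt2 <- make_life_table(max_age = 120, gompertz = c(1e-4, 0.09))
  adj3 <- adjust_for_background_mortality(cur, lt2, aw)
  expect_true(all(adj3$values <= cur$values + 1e-12))
  brute <- 1
  out <- 1
  for (t in 1:20) {
    p_mod <- 1 - cur$values[t + 1] / cur$values[t]
    q <- lt2$qx[lt2$age == 60 + t - 1]
    brute <- c(brute, out <- out * (1 - max(p_mod, q)))
  }
  expect_equal(adj3$values, brute, tolerance = 1e-12)

  # life table must cover attained ages; DFS curves are refused
  short <- make_life_table(max_age = 65)
  expect_error(adjust_for_background_mortality(cur, short, aw), "age")
  dfs <- survival_curve(rep(1, 5), endpoint = "DFS")
  expect_error(adjust_for_background_mortality(dfs, lt0, aw), "OS")
})

test_that("DFS is capped at OS pointwise with a flag", {
  os <- survival_curve(c(1, 0.9, 0.8), endpoint = "OS")
  dfs <- survival_curve(c(1, 0.95, 0.85), endpoint = "DFS")
  capped <- cap_dfs_at_os(dfs, os)
  expect_equal(capped$values, c(1, 0.9, 0.8))
  expect_true(attr(capped, "capped"))
  ok <- cap_dfs_at_os(survival_curve(c(1, 0.8, 0.7), endpoint = "DFS"), os)
  expect_false(attr(ok, "capped"))
})
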
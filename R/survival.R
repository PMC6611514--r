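## Survival modelling: Weibull parameters, survival curves, pseudo-IPD
## reconstruction from digitized Kaplan-Meier curves, right-censored MLE,
## curve stitching and background-mortality adjustment.

#' Weibull survival parameters
#'
#' Container for the two-parameter Weibull survival function
#' \eqn{S(t) = \exp\{-(t/\lambda)^k\}} with shape \eqn{k > 0} and scale
#' \eqn{\lambda > 0}.  This matches the parameterization of
#' [stats::rweibull()]; `shape = 1` reduces to the exponential
#' distribution with mean `scale`.
#'
#' @param shape Shape parameter \eqn{k > 0}.
#' @param scale Scale parameter \eqn{\lambda > 0}, in years.
#' @return An object of class `weibull_params`.
#' @examples
#' wp <- weibull_params(1.4, 9)
#' survival_at(wp, c(0, 5, 9))
#' @export
weibull_params <- function(shape, scale) {
  check_number(shape, "shape", lower = 0, strict_lower = TRUE)
  check_number(scale, "scale", lower = 0, strict_lower = TRUE)
  structure(list(shape = shape, scale = scale), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull survival parameters: shape = %.4g, scale = %.4g\n",
              x$shape, x$scale))
  if (!is.null(attr(x, "loglik")))
    cat(sprintf("  log-likelihood %.4f on %d records (%d events)\n",
                attr(x, "loglik"), attr(x, "n"), attr(x, "n_events")))
  invisible(x)
}

#' Weibull survival probability
#'
#' @param params A [weibull_params()] object.
#' @param t Vector of non-negative times (years).
#' @return `exp(-(t/scale)^shape)`, vectorized over `t`.
#' @export
survival_at <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop_her2("'t' must be finite and >= 0")
  exp(-(t / params$scale)^params$shape)
}

#' Event-time data set
#'
#' Individual records of follow-up time and event indicator, the unit of
#' data for Kaplan-Meier estimation and parametric fitting.
#'
#' @param time Non-negative follow-up times in years.
#' @param event Logical (or 0/1) event indicator; `FALSE` = right-censored.
#' @return A `data.frame` of class `event_data` with columns `time`, `event`.
#' @export
event_data <- function(time, event) {
  if (any(!is.finite(time)) || any(time < 0))
    stop_her2("'time' must be finite and >= 0")
  event <- as.logical(event)
  if (any(is.na(event))) stop_her2("'event' must be logical without NA")
  structure(data.frame(time = as.numeric(time), event = event),
            class = c("event_data", "data.frame"))
}

#' Annual-grid survival curve
#'
#' Survival probabilities on the integer-year grid `t = 0, 1, ..., horizon`,
#' for one endpoint (overall or disease-free survival) of one treatment
#' arm.  Curves may combine an empirical Kaplan-Meier segment with a
#' parametric Weibull tail (see [stitch_curve()]) and may have been
#' adjusted for background mortality.
#'
#' @param values Numeric vector of survival probabilities at
#'   `t = 0, ..., length(values) - 1`; must start at 1, be non-increasing
#'   and lie in `[0, 1]`.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param arm Arm label, conventionally `"T+CT"` or `"CT"`.
#' @param switch_time Years at which the curve switches from empirical to
#'   parametric values (`NA` if not stitched).
#' @param mortality_adjusted Has [adjust_for_background_mortality()] been
#'   applied?
#' @return An object of class `survival_curve`.
#' @export
survival_curve <- function(values, endpoint = c("OS", "DFS"),
                           arm = "unspecified", switch_time = NA_real_,
                           mortality_adjusted = FALSE) {
  endpoint <- match.arg(endpoint)
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stop_her2("'values' must be a non-empty finite numeric vector")
  if (abs(values[1L] - 1) > 1e-8)
    stop_her2("a survival curve must start at S(0) = 1")
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop_her2("survival values must lie in [0, 1]")
  if (any(diff(values) > 1e-9))
    stop_her2("survival values must be non-increasing")
  values <- pmin(pmax(values, 0), 1)
  values[1L] <- 1
  structure(list(values = values, endpoint = endpoint, arm = arm,
                 switch_time = switch_time,
                 mortality_adjusted = isTRUE(mortality_adjusted)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("%s survival curve, arm %s: %d annual points (t = 0..%d)\n",
              x$endpoint, x$arm, length(x$values), length(x$values) - 1L))
  if (!is.na(x$switch_time))
    cat(sprintf("  empirical to t = %g, Weibull tail beyond\n", x$switch_time))
  if (x$mortality_adjusted) cat("  background-mortality adjusted\n")
  invisible(x)
}

## Extract values whether given a curve object or a bare numeric vector.
curve_values <- function(x) {
  if (inherits(x, "survival_curve")) x$values else as.numeric(x)
}

#' Curve horizon in years
#' @param curve A [survival_curve()].
#' @return Number of annual steps covered (length of values minus one).
#' @export
curve_horizon <- function(curve) length(curve_values(curve)) - 1L

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Turns the step coordinates of a published Kaplan-Meier curve (plus
#' optional numbers-at-risk anchors) back into individual event/censoring
#' times whose Kaplan-Meier estimate reproduces the input curve, in the
#' spirit of the standard digitized-curve reconstruction algorithms.
#' Events within each digitized interval are allocated at the step time;
#' censorings implied by the at-risk anchors are placed immediately after
#' the events of the same step.  All subjects still at risk after the
#' last digitized time are censored there.
#'
#' @param km_points `data.frame` with columns `time` and `survival`
#'   (non-increasing step values; a `time = 0, survival = 1` row is
#'   implied if absent).  A column `n_risk` is used as at-risk anchors if
#'   present and `at_risk` is not given.
#' @param n_total Number of subjects at time 0.
#' @param at_risk Optional `data.frame` with columns `time`, `n_risk`:
#'   number still at risk entering the interval that starts at `time`.
#' @return An [event_data()] object with `n_total` rows.
#' @export
reconstruct_pseudo_ipd <- function(km_points, n_total, at_risk = NULL) {
  check_number(n_total, "n_total", lower = 1)
  km_points <- as.data.frame(km_points)
  if (!all(c("time", "survival") %in% names(km_points)))
    stop_her2("'km_points' needs columns 'time' and 'survival'")
  if (is.null(at_risk) && "n_risk" %in% names(km_points))
    at_risk <- km_points[, c("time", "n_risk")]
  km_points <- km_points[order(km_points$time), , drop = FALSE]
  if (km_points$time[1L] > 0)
    km_points <- rbind(data.frame(time = 0, survival = 1,
                                  km_points[1, setdiff(names(km_points),
                                                       c("time", "survival")),
                                            drop = FALSE]),
                       km_points)
  if (any(diff(km_points$survival) > 1e-9))
    stop_her2("digitized survival values must be non-increasing")
  if (abs(km_points$survival[1L] - 1) > 1e-6)
    stop_her2("digitized curve must start at survival 1")

  anchor <- function(t) {
    if (is.null(at_risk)) return(NA_real_)
    i <- which(abs(at_risk$time - t) < 1e-9)
    if (length(i)) at_risk$n_risk[i[1L]] else NA_real_
  }

  times <- km_points$time
  surv <- km_points$survival
  n_cur <- n_total
  s_km <- 1
  ev_t <- numeric(0); cn_t <- numeric(0)
  for (i in seq_along(times)[-1L]) {
    d <- 0
    if (n_cur > 0) {
      d <- round_half_up(n_cur * (1 - surv[i] / s_km))
      d <- min(max(d, 0), n_cur)
    }
    if (d > 0) {
      ev_t <- c(ev_t, rep(times[i], d))
      s_km <- s_km * (1 - d / n_cur)
      n_cur <- n_cur - d
    }
    a <- anchor(times[i])
    if (!is.na(a) && i < length(times)) {
      cens <- n_cur - a
      if (cens < -0.5)
        warning("at-risk anchors inconsistent with survival drops; ",
                "proceeding best-effort", call. = FALSE)
      cens <- min(max(round_half_up(cens), 0), n_cur)
      if (cens > 0) {
        cn_t <- c(cn_t, rep(times[i], cens))
        n_cur <- n_cur - cens
      }
    }
  }
  if (n_cur > 0) cn_t <- c(cn_t, rep(times[length(times)], n_cur))
  event_data(c(ev_t, cn_t),
             c(rep(TRUE, length(ev_t)), rep(FALSE, length(cn_t))))
}

## Right-censored Weibull log-likelihood:
##   sum_events log h(t) + sum_all log S(t)
## with h(t) = (k/lam)(t/lam)^(k-1), log S(t) = -(t/lam)^k.
weibull_loglik <- function(shape, scale, time, event) {
  z <- (time / scale)^shape
  ll <- -sum(z)
  te <- time[event]
  if (length(te))
    ll <- ll + sum(log(shape / scale) + (shape - 1) * log(te / scale))
  ll
}

#' Fit a Weibull survival model by right-censored maximum likelihood
#'
#' Maximizes the right-censored Weibull log-likelihood
#' \eqn{\sum_{events} \log h(t_i) + \sum_{all} \log S(t_i)} over
#' `(shape, scale)` on the log scale with BFGS.  With `shape` supplied,
#' the scale MLE has the closed form
#' \eqn{\hat\lambda = (\sum t_i^k / d)^{1/k}} (for `shape = 1` this is
#' total follow-up time divided by the number of events, the exponential
#' MLE).
#'
#' @param data An [event_data()] object (or data.frame with `time`,
#'   `event`).  At least two events are required; event times must be
#'   positive.
#' @param shape Optional fixed shape; if given only the scale is estimated.
#' @return A [weibull_params()] object with attributes `loglik`, `n`,
#'   `n_events`, `se` (standard errors of shape and scale, delta method
#'   from the observed information on the log scale) and `vcov`.
#' @export
fit_weibull_mle <- function(data, shape = NULL) {
  data <- as.data.frame(data)
  time <- as.numeric(data$time)
  event <- as.logical(data$event)
  if (any(time[event] <= 0))
    stop_her2("event times must be strictly positive")
  d <- sum(event)
  if (d < 2L && is.null(shape))
    stop_her2("at least 2 events are required to fit both parameters")
  if (d < 1L) stop_her2("at least 1 event is required")

  if (!is.null(shape)) {
    check_number(shape, "shape", lower = 0, strict_lower = TRUE)
    scale <- (sum(time^shape) / d)^(1 / shape)
    out <- weibull_params(shape, scale)
    attr(out, "loglik") <- weibull_loglik(shape, scale, time, event)
    attr(out, "n") <- length(time); attr(out, "n_events") <- d
    attr(out, "shape_fixed") <- TRUE
    return(out)
  }

  negll <- function(p) -weibull_loglik(exp(p[1L]), exp(p[2L]), time, event)
  ## moment-flavoured starting values: exponential scale, shape 1
  start <- c(0, log(sum(time) / d))
  fit <- optim(start, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    g <- tryCatch(max(abs(numDeriv_grad(negll, fit$par))), error = function(e) NA)
    stop_her2(sprintf(
      "Weibull MLE did not converge (optim code %d, final gradient norm %s)",
      fit$convergence, format(g)))
  }
  shape_hat <- exp(fit$par[1L]); scale_hat <- exp(fit$par[2L])
  out <- weibull_params(shape_hat, scale_hat)
  attr(out, "loglik") <- -fit$value
  attr(out, "n") <- length(time); attr(out, "n_events") <- d
  vc_log <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(vc_log)) {
    ## delta method back from the log scale
    J <- diag(c(shape_hat, scale_hat))
    vc <- J %*% vc_log %*% J
    dimnames(vc) <- list(c("shape", "scale"), c("shape", "scale"))
    attr(out, "vcov") <- vc
    attr(out, "se") <- sqrt(pmax(diag(vc), 0))
  }
  out
}

## central finite-difference gradient, only used for error reporting
numDeriv_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Stitch an empirical Kaplan-Meier segment to a Weibull tail
#'
#' Builds the annual-grid curve used for extrapolation beyond trial
#' follow-up: the empirical (digitized) Kaplan-Meier values are kept up to
#' `switch_time`, and the parametric Weibull survival is used beyond it,
#' rescaled by `km(switch) / S_param(switch)` so that the curve is
#' continuous at the switch.  `switch_time = 0` gives the pure parametric
#' curve (the "parametric from the start" sensitivity mode).
#'
#' @param km Numeric vector of empirical annual survival values at
#'   `t = 0, 1, ...` (must cover `0..switch_time`), or a
#'   [survival_curve()].
#' @param params [weibull_params()] for the parametric tail.
#' @param switch_time Integer year at which to switch (>= 0).
#' @param horizon Last year of the output grid.
#' @inheritParams survival_curve
#' @return A [survival_curve()] on `t = 0..horizon`.
#' @export
stitch_curve <- function(km, params, switch_time, horizon,
                         endpoint = c("OS", "DFS"), arm = "unspecified") {
  endpoint <- match.arg(endpoint)
  check_number(switch_time, "switch_time", lower = 0)
  check_number(horizon, "horizon", lower = switch_time)
  kmv <- curve_values(km)
  if (switch_time > 0 && length(kmv) < switch_time + 1L)
    stop_her2("'km' must cover t = 0..switch_time")
  tt <- 0:horizon
  sw <- as.integer(switch_time)
  s_par <- survival_at(params, tt)
  if (sw == 0) {
    vals <- s_par
  } else {
    s_sw <- survival_at(params, sw)
    if (s_sw <= 0) stop_her2("parametric survival is 0 at the switch time")
    factor <- kmv[sw + 1L] / s_sw
    vals <- c(kmv[1:(sw + 1L)],
              s_par[(sw + 2L):(horizon + 1L)] * factor)
    if (any(vals > 1 + 1e-9))
      stop_her2("rescaled parametric tail exceeds 1; check inputs")
  }
  survival_curve(vals, endpoint = endpoint, arm = arm,
                 switch_time = switch_time)
}

#' Adjust an overall-survival curve for background mortality
#'
#' Applies the hazard-maximum rule per annual cycle: the transition death
#' probability is the larger of the model-implied probability
#' `1 - S(t)/S(t-1)` and the cohort-weighted general-population death
#' probability at the attained age, where attained age = age at diagnosis
#' + years since diagnosis.  This guarantees a proper survival function
#' never above the disease curve, with influence confined to the tail
#' when disease mortality dominates.
#'
#' @param curve An OS [survival_curve()].
#' @param life_table A [make_life_table()] table (`age`, `qx`).
#' @param age_weights `data.frame` with columns `age` (age at diagnosis)
#'   and `weight` (summing to 1), or a single age.
#' @return The adjusted [survival_curve()] (`mortality_adjusted = TRUE`),
#'   pointwise no larger than the input.
#' @export
adjust_for_background_mortality <- function(curve, life_table, age_weights) {
  stopifnot(inherits(curve, "survival_curve"))
  if (curve$endpoint != "OS")
    stop_her2("background-mortality adjustment applies to OS curves only")
  aw <- normalize_age_weights(age_weights)
  v <- curve$values
  horizon <- length(v) - 1L
  out <- numeric(length(v)); out[1L] <- 1
  for (t in seq_len(horizon)) {
    p_model <- if (v[t] > 0) 1 - v[t + 1L] / v[t] else 0
    q_bg <- weighted_background_q(life_table, aw$age + (t - 1), aw$weight)
    p <- max(p_model, q_bg)
    out[t + 1L] <- out[t] * (1 - p)
  }
  survival_curve(out, endpoint = "OS", arm = curve$arm,
                 switch_time = curve$switch_time, mortality_adjusted = TRUE)
}

normalize_age_weights <- function(age_weights) {
  if (is.numeric(age_weights) && is.null(dim(age_weights)) &&
      length(age_weights) == 1L)
    return(list(age = age_weights, weight = 1))
  aw <- as.data.frame(age_weights)
  if (!all(c("age", "weight") %in% names(aw)))
    stop_her2("'age_weights' needs columns 'age' and 'weight'")
  if (any(aw$weight < 0)) stop_her2("age weights must be non-negative")
  s <- sum(aw$weight)
  if (abs(s - 1) > 1e-6)
    stop_her2("age weights must sum to 1")
  list(age = aw$age, weight = aw$weight / s)
}

## Cohort-weighted annual death probability at given attained ages.
weighted_background_q <- function(life_table, ages, weights) {
  lt <- as.data.frame(life_table)
  idx <- match(round(ages), lt$age)
  if (any(is.na(idx)))
    stop_her2(sprintf(
      "life table does not cover attained age(s) %s",
      paste(round(ages)[is.na(idx)], collapse = ", ")))
  sum(weights * lt$qx[idx])
}

#' Cap disease-free survival at overall survival
#'
#' Enforces `DFS(t) <= OS(t)` pointwise after any independent adjustment
#' of the two curves, flagging whether the cap was triggered anywhere.
#'
#' @param dfs,os [survival_curve()] objects of equal horizon.
#' @return The capped DFS curve, with attribute `capped` (logical).
#' @export
cap_dfs_at_os <- function(dfs, os) {
  vd <- curve_values(dfs); vo <- curve_values(os)
  if (length(vd) != length(vo))
    stop_her2("DFS and OS curves must share the same grid")
  capped <- any(vd > vo + 1e-12)
  out <- survival_curve(pmin(vd, vo), endpoint = "DFS",
                        arm = if (inherits(dfs, "survival_curve")) dfs$arm
                              else "unspecified",
                        switch_time = if (inherits(dfs, "survival_curve"))
                          dfs$switch_time else NA_real_,
                        mortality_adjusted =
                          inherits(dfs, "survival_curve") &&
                          dfs$mortality_adjusted)
  attr(out, "capped") <- capped
  out
}
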
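## Progression accounting: expected new progressions per year from the
## OS/DFS pair, by the Markov-cohort and partitioned-survival methods,
## with a recurrence-window cap.

#' Progression series container
#'
#' @param new_progressions Expected new progressions per year since
#'   diagnosis (year 1 = first annual cycle).
#' @param method `"Markov"` or `"PSM"`.
#' @param cap_years Recurrence window: the series is identically zero
#'   beyond this many years since diagnosis.
#' @param n_floored How many raw increments were negative and floored.
#' @return `data.frame` of class `progression_series` with columns
#'   `years_since_dx`, `new_progressions`; attributes `method`,
#'   `cap_years`, `n_floored`.
#' @export
progression_series <- function(new_progressions, method, cap_years,
                               n_floored = 0L) {
  if (any(new_progressions < 0))
    stop_her2("new progressions must be >= 0")
  out <- data.frame(years_since_dx = seq_along(new_progressions),
                    new_progressions = as.numeric(new_progressions))
  class(out) <- c("progression_series", "data.frame")
  attr(out, "method") <- method
  attr(out, "cap_years") <- cap_years
  attr(out, "n_floored") <- n_floored
  out
}

check_progression_curves <- function(os, dfs) {
  vo <- curve_values(os); vd <- curve_values(dfs)
  if (length(vo) != length(vd))
    stop_her2("OS and DFS curves must share the same annual grid")
  if (any(vd > vo + 1e-9))
    stop_her2("DFS exceeds OS; cap DFS at OS first (see cap_dfs_at_os)")
  list(os = vo, dfs = pmin(vd, vo))
}

#' New progressions by the Markov-cohort method
#'
#' Per annual cycle, new progressions = (those leaving the disease-free
#' state according to DFS) minus (deaths according to OS):
#' `n0 * [(DFS(t-1) - DFS(t)) - (OS(t-1) - OS(t))]`.  Negative raw
#' increments (curve-crossing noise, e.g. from digitization) are floored
#' at zero and counted.  The series is zeroed beyond `cap_years` since
#' diagnosis, reflecting the assumption that recurrences are confined to
#' the early post-treatment window.
#'
#' @param os,dfs [survival_curve()] objects (or numeric annual vectors)
#'   with `DFS <= OS` pointwise.
#' @param n0 Cohort size at diagnosis.
#' @param cap_years Recurrence window in years since diagnosis; use the
#'   curve horizon to disable the cap.
#' @return A [progression_series()].
#' @export
new_progressions_markov <- function(os, dfs, n0, cap_years = 7) {
  check_number(n0, "n0", lower = 0)
  cv <- check_progression_curves(os, dfs)
  tmax <- length(cv$os) - 1L
  t <- seq_len(tmax)
  raw <- n0 * ((cv$dfs[t] - cv$dfs[t + 1L]) - (cv$os[t] - cv$os[t + 1L]))
  floored <- sum(raw < -1e-12)
  newp <- pmax(raw, 0)
  newp[t > cap_years] <- 0
  progression_series(newp, "Markov", cap_years, floored)
}

#' New progressions by the partitioned-survival method
#'
#' The progressed-state prevalence is the area between the curves at
#' each grid point, `prev(t) = n0 * (OS(t) - DFS(t))`.  New progressions
#' are the prevalence increments net of exits from the progressed state:
#' `new(t) = max(0, prev(t) - prev(t-1) * (1 - m(t)))`, where `m(t)` is
#' the annual mortality of progressed patients.  By default `m(t)` is
#' the cohort OS hazard `1 - OS(t)/OS(t-1)` (override with a scalar or
#' per-year vector).  With `progressed_mortality = 0` the formula
#' reduces to the raw prevalence increments, which coincide exactly with
#' the Markov-cohort series (the two decompositions agree when no
#' progressed patient exits within the window).
#'
#' @inheritParams new_progressions_markov
#' @param progressed_mortality Annual death probability in the
#'   progressed state: `NULL` (default, cohort OS hazard), a scalar, or
#'   a vector of length `horizon`.
#' @return A [progression_series()].
#' @export
new_progressions_psm <- function(os, dfs, n0, cap_years = 7,
                                 progressed_mortality = NULL) {
  check_number(n0, "n0", lower = 0)
  cv <- check_progression_curves(os, dfs)
  tmax <- length(cv$os) - 1L
  prev <- n0 * (cv$os - cv$dfs)
  t <- seq_len(tmax)
  m <- if (is.null(progressed_mortality)) {
    ifelse(cv$os[t] > 0, 1 - cv$os[t + 1L] / cv$os[t], 0)
  } else {
    check_proportion(progressed_mortality, "progressed_mortality")
    rep_len(progressed_mortality, tmax)
  }
  raw <- prev[t + 1L] - prev[t] * (1 - m)
  floored <- sum(raw < -1e-12)
  newp <- pmax(raw, 0)
  newp[t > cap_years] <- 0
  progression_series(newp, "PSM", cap_years, floored)
}

#' Dispatch on the configured progression method
#' @inheritParams new_progressions_psm
#' @param method `"PSM"` or `"Markov"`.
#' @return A [progression_series()].
#' @export
new_progressions <- function(os, dfs, n0, method = c("PSM", "Markov"),
                             cap_years = 7, progressed_mortality = NULL) {
  method <- match.arg(method)
  if (method == "PSM")
    new_progressions_psm(os, dfs, n0, cap_years, progressed_mortality)
  else
    new_progressions_markov(os, dfs, n0, cap_years)
}
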
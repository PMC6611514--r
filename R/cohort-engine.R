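## Cohort engine: annual-cycle traces per incidence cohort, half-cycle
## (trapezoid) accumulation of life years and disease-free life years,
## temporal-preference discounting anchored at a reference calendar
## year, the general-population comparator, and aggregation across
## cohorts into scenario totals.

#' Discount a calendar-year series
#'
#' Applies the annual temporal-preference rate relative to a reference
#' calendar year: values in years at or before the reference year are
#' unchanged (benefits and costs already realized are not discounted);
#' values `d` years beyond it are divided by `(1 + rate)^d`.  Set
#' `discount_past = TRUE` to discount (inflate) past years symmetrically
#' instead.
#'
#' @param values Numeric series.
#' @param years Calendar year of each value.
#' @param rate Annual discount rate (>= 0).
#' @param reference_year Calendar year taken as the present.
#' @param discount_past Discount years before the reference year too?
#' @return The discounted series.
#' @export
discount <- function(values, years, rate, reference_year,
                     discount_past = FALSE) {
  check_number(rate, "rate", lower = 0)
  d <- years - reference_year
  if (!discount_past) d <- pmax(d, 0)
  values / (1 + rate)^d
}

#' Build the annual trace of one incidence cohort
#'
#' Expected state occupancy and person-year accumulation for a cohort of
#' `n0` patients diagnosed in `start_year`, followed to `horizon_year`:
#' `alive(t) = n0 * OS(t)`, `disease_free(t) = n0 * DFS(t)`, and life
#' years per annual cycle by the trapezoid (half-cycle) rule
#' `n0 * (S(t-1) + S(t)) / 2`.  The cycle from `t-1` to `t` is
#' attributed to calendar year `start_year + t - 1` (life years in the
#' diagnosis year count from the start of that calendar year).  New
#' progressions come from the configured progression method.
#'
#' @param n0 Cohort size at diagnosis (>= 0).
#' @param os,dfs [survival_curve()] objects covering at least
#'   `horizon_year - start_year` annual steps.
#' @param start_year,horizon_year Calendar years; the horizon must not
#'   precede the start.
#' @param discount_rate,reference_year,discount_past Passed to
#'   [discount()].
#' @param progression_method,cap_years,progressed_mortality Passed to
#'   [new_progressions()].
#' @param scenario Label stored on the trace.
#' @return `data.frame` of class `cohort_trace` with one row per
#'   calendar year `start_year .. horizon_year - 1` and columns
#'   `cohort_year`, `calendar_year`, `years_since_dx`, `alive`,
#'   `disease_free`, `new_progressions`, `ly`, `dfly`, `ly_disc`,
#'   `dfly_disc`.
#' @export
build_cohort_trace <- function(n0, os, dfs, start_year, horizon_year,
                               discount_rate = 0,
                               reference_year = start_year,
                               discount_past = FALSE,
                               progression_method = "PSM",
                               cap_years = 7,
                               progressed_mortality = NULL,
                               scenario = "unspecified") {
  check_number(n0, "n0", lower = 0)
  if (horizon_year < start_year)
    stop_her2("'horizon_year' precedes 'start_year'")
  T <- as.integer(horizon_year - start_year)
  vo <- curve_values(os); vd <- curve_values(dfs)
  if (length(vo) < T + 1L || length(vd) < T + 1L)
    stop_her2(sprintf("curves must cover %d annual steps", T))
  vo <- vo[seq_len(T + 1L)]; vd <- pmin(vd[seq_len(T + 1L)], vo)
  t <- seq_len(T)
  prog <- if (T > 0)
    new_progressions(vo, vd, n0, method = progression_method,
                     cap_years = cap_years,
                     progressed_mortality = progressed_mortality)$new_progressions
  else numeric(0)
  cal <- start_year + t - 1L
  ly <- n0 * (vo[t] + vo[t + 1L]) / 2
  dfly <- n0 * (vd[t] + vd[t + 1L]) / 2
  out <- data.frame(cohort_year = rep(as.integer(start_year), T),
                    calendar_year = cal, years_since_dx = t,
                    alive = n0 * vo[t + 1L],
                    disease_free = n0 * vd[t + 1L],
                    new_progressions = prog,
                    ly = ly, dfly = dfly,
                    ly_disc = discount(ly, cal, discount_rate,
                                       reference_year, discount_past),
                    dfly_disc = discount(dfly, cal, discount_rate,
                                         reference_year, discount_past))
  class(out) <- c("cohort_trace", "data.frame")
  attr(out, "n0") <- n0
  attr(out, "scenario") <- scenario
  attr(out, "horizon_year") <- as.integer(horizon_year)
  out
}

#' Life years of the general-population comparator
#'
#' Expected (discounted) life years the target cohorts would have
#' accumulated under general-population mortality alone: per cohort, the
#' survival function is built purely from the life-table death
#' probabilities at the attained ages (cohort-weighted over the age
#' distribution at diagnosis), and person-years are accumulated and
#' discounted exactly like the disease traces.
#'
#' @param cohorts A [target_cohorts()] object.
#' @param life_table A [make_life_table()] table.
#' @param horizon_year Last calendar year of follow-up.
#' @param rate,reference_year,discount_past Discounting, as in
#'   [discount()].
#' @param age_weights `data.frame(age, weight)` at diagnosis; default is
#'   taken from the cohorts attribute, else [default_age_weights()].
#' @return Total (discounted) life years, with attribute `by_cohort`.
#' @export
general_population_ly <- function(cohorts, life_table, horizon_year,
                                  rate = 0, reference_year = horizon_year,
                                  discount_past = FALSE,
                                  age_weights = NULL) {
  age_weights <- age_weights %||% attr(cohorts, "age_weights") %||%
    default_age_weights()
  aw <- normalize_age_weights(age_weights)
  by_cohort <- numeric(nrow(cohorts))
  for (i in seq_len(nrow(cohorts))) {
    y0 <- cohorts$cohort_year[i]
    n0 <- cohorts$target_n[i]
    T <- as.integer(horizon_year - y0)
    if (T <= 0) next
    q <- vapply(seq_len(T), function(t)
      weighted_background_q(life_table, aw$age + (t - 1), aw$weight),
      numeric(1))
    s <- c(1, cumprod(1 - q))
    t <- seq_len(T)
    ly <- n0 * (s[t] + s[t + 1L]) / 2
    by_cohort[i] <- sum(discount(ly, y0 + t - 1L, rate, reference_year,
                                 discount_past))
  }
  out <- sum(by_cohort)
  attr(out, "by_cohort") <- setNames(by_cohort, cohorts$cohort_year)
  out
}

#' Scenario result totals
#'
#' @param total_ly,total_dfly Discounted life-year and disease-free
#'   life-year totals.
#' @param total_cost Total discounted direct cost (EUR).
#' @param cost_by_category Named numeric vector of discounted costs by
#'   category.
#' @param total_ly_undisc,total_dfly_undisc Undiscounted twins.
#' @param cohorts Optional per-cohort breakdown `data.frame`.
#' @param label Scenario label.
#' @return A list of class `scenario_result`.
#' @export
scenario_result <- function(total_ly, total_dfly, total_cost = NA_real_,
                            cost_by_category = NULL,
                            total_ly_undisc = NA_real_,
                            total_dfly_undisc = NA_real_,
                            cohorts = NULL, label = "scenario") {
  structure(list(total_ly = total_ly, total_dfly = total_dfly,
                 total_cost = total_cost,
                 cost_by_category = cost_by_category,
                 total_ly_undisc = total_ly_undisc,
                 total_dfly_undisc = total_dfly_undisc,
                 cohorts = cohorts, label = label),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s'\n", x$label))
  cat(sprintf("  life years (discounted): %.0f\n", x$total_ly))
  cat(sprintf("  disease-free life years (discounted): %.0f\n",
              x$total_dfly))
  if (is.finite(x$total_cost))
    cat(sprintf("  total direct cost: EUR %.0f\n", x$total_cost))
  if (!is.null(x$cost_by_category)) {
    for (nm in names(x$cost_by_category))
      cat(sprintf("    %s: EUR %.0f\n", nm, x$cost_by_category[[nm]]))
  }
  invisible(x)
}

#' Aggregate cohort traces (and cost streams) into scenario totals
#'
#' Sums the discounted and undiscounted life-year quantities over all
#' traces, and the discounted costs per category over all cost streams.
#' Totals equal the sums over cohorts exactly (conservation).  All
#' traces must share the same horizon year.
#'
#' @param traces List of [build_cohort_trace()] results.
#' @param cost_streams Optional list of cost-stream `data.frame`s (see
#'   [ancillary_costs()]); rows must have `category`, `cost`,
#'   `cost_disc`.
#' @param label Scenario label.
#' @return A [scenario_result()].
#' @export
aggregate_traces <- function(traces, cost_streams = NULL,
                             label = "scenario") {
  if (length(traces) == 0L)
    return(scenario_result(0, 0, if (is.null(cost_streams)) NA_real_ else 0,
                           label = label))
  horizons <- vapply(traces, function(tr) attr(tr, "horizon_year"),
                     integer(1))
  if (length(unique(horizons)) != 1L)
    stop_her2("traces have mismatched horizon years: ",
              paste(unique(horizons), collapse = ", "))
  per <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cohort_year = if (nrow(tr)) tr$cohort_year[1L] else NA_integer_,
               ly = sum(tr$ly), dfly = sum(tr$dfly),
               ly_disc = sum(tr$ly_disc), dfly_disc = sum(tr$dfly_disc))))
  total_cost <- NA_real_
  by_cat <- NULL
  if (!is.null(cost_streams) && length(cost_streams)) {
    cs <- do.call(rbind, cost_streams)
    by_cat <- tapply(cs$cost_disc, cs$category, sum)
    by_cat <- setNames(as.numeric(by_cat), names(by_cat))
    total_cost <- sum(by_cat)
  }
  scenario_result(sum(per$ly_disc), sum(per$dfly_disc), total_cost,
                  cost_by_category = by_cat,
                  total_ly_undisc = sum(per$ly),
                  total_dfly_undisc = sum(per$dfly),
                  cohorts = per, label = label)
}

#' Incremental difference between two scenario results
#'
#' Element-wise `a - b`: incremental life years, disease-free life
#' years, total cost and cost by category.
#'
#' @param a,b [scenario_result()] objects.
#' @return A list of class `scenario_increment` with `inc_ly`,
#'   `inc_dfly`, `inc_cost`, `inc_by_category`.
#' @export
scenario_diff <- function(a, b) {
  stopifnot(inherits(a, "scenario_result"), inherits(b, "scenario_result"))
  by_cat <- NULL
  if (!is.null(a$cost_by_category) && !is.null(b$cost_by_category)) {
    cats <- union(names(a$cost_by_category), names(b$cost_by_category))
    get0 <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
    by_cat <- setNames(vapply(cats, function(nm)
      get0(a$cost_by_category, nm) - get0(b$cost_by_category, nm),
      numeric(1)), cats)
  }
  structure(list(inc_ly = a$total_ly - b$total_ly,
                 inc_dfly = a$total_dfly - b$total_dfly,
                 inc_cost = a$total_cost - b$total_cost,
                 inc_by_category = by_cat,
                 labels = c(a$label, b$label)),
            class = "scenario_increment")
}

#' @export
print.scenario_increment <- function(x, ...) {
  cat(sprintf("Increment '%s' vs '%s'\n", x$labels[1L], x$labels[2L]))
  cat(sprintf("  LYG: %.0f   DFLYG: %.0f\n", x$inc_ly, x$inc_dfly))
  if (is.finite(x$inc_cost))
    cat(sprintf("  incremental cost: EUR %.0f\n", x$inc_cost))
  invisible(x)
}

#' Mean cohort follow-up to the horizon
#'
#' Average of `horizon_year - cohort_year` over the cohorts — the mean
#' follow-up the chosen horizon guarantees (23.5 years for cohorts
#' 2006-2017 followed to 2035).
#'
#' @param cohort_years Vector of cohort calendar years.
#' @param horizon_year Horizon calendar year.
#' @return Mean follow-up in years.
#' @export
mean_followup <- function(cohort_years, horizon_year) {
  mean(horizon_year - cohort_years)
}
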
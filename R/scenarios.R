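## Scenario assembly: market-share-weighted real-world runs, pure
## full-use and chemotherapy-only runs, incremental results and ICERs,
## and the deterministic sensitivity-analysis driver.

#' Market-share series
#'
#' Per cohort year, the proportion of target patients receiving
#' adjuvant trastuzumab, and among the treated the fraction on the
#' subcutaneous formulation (`sc_share`, necessarily 0 before its 2015
#' availability).
#'
#' @param year Cohort calendar years.
#' @param share Proportion treated with trastuzumab, in `[0, 1]`.
#' @param sc_share Proportion of the treated on SC, in `[0, 1]`; must be
#'   0 before 2015.
#' @return `data.frame` of class `market_share_series`.
#' @export
market_share_series <- function(year, share, sc_share = 0) {
  check_proportion(share, "share")
  check_proportion(sc_share, "sc_share")
  out <- data.frame(year = as.integer(year), share = share,
                    sc_share = rep_len(sc_share, length(year)))
  if (any(out$sc_share[out$year < 2015] > 0))
    stop_her2("SC share must be 0 before 2015")
  class(out) <- c("market_share_series", "data.frame")
  out
}

lookup_share <- function(shares, year) {
  i <- match(year, shares$year)
  if (is.na(i)) stop_her2(sprintf("no market share for year %d", year))
  list(share = shares$share[i], sc_share = shares$sc_share[i])
}

#' Assemble the model's efficacy curves
#'
#' For each endpoint/arm, stitches the empirical annual Kaplan-Meier
#' values to the Weibull tail at the configured switch time, adjusts the
#' OS curves for background mortality (attained-age hazard-maximum rule)
#' and caps DFS at OS pointwise.
#'
#' @param km_inputs Named list with elements `os_tct`, `os_ct`,
#'   `dfs_tct`, `dfs_ct`; each a list with `km` (numeric annual survival
#'   values at t = 0, 1, ... or a `data.frame(time, survival)`) and
#'   `params` (a [weibull_params()]).
#' @param cfg A `her2_config` (uses `switch_time`, `horizon_year`,
#'   `cohort_years`).
#' @param life_table Optional [make_life_table()] table for the OS
#'   background-mortality adjustment (skipped when `NULL`).
#' @param age_weights Age-at-diagnosis weights for the attained-age
#'   calculation (default [default_age_weights()]).
#' @param horizon_len Length of the curve grid in years (default: from
#'   the first cohort year to the horizon).
#' @return Named list of four [survival_curve()]s.
#' @export
prepare_efficacy_curves <- function(km_inputs, cfg, life_table = NULL,
                                    age_weights = NULL,
                                    horizon_len = NULL) {
  horizon_len <- horizon_len %||%
    (cfg$horizon_year - min(cfg$cohort_years))
  age_weights <- age_weights %||% default_age_weights()
  annual_km <- function(km) {
    if (is.data.frame(km)) {
      i <- match(0:floor(max(km$time)), round(km$time, 6))
      km$survival[i[!is.na(i)]]
    } else as.numeric(km)
  }
  build <- function(key, endpoint, arm) {
    inp <- km_inputs[[key]]
    if (is.null(inp)) stop_her2("km_inputs$", key, " is missing")
    kmv <- annual_km(inp$km)
    sw <- min(cfg$switch_time, length(kmv) - 1L)
    stitch_curve(kmv, inp$params, sw, horizon_len,
                 endpoint = endpoint, arm = arm)
  }
  os_tct <- build("os_tct", "OS", "T+CT")
  os_ct <- build("os_ct", "OS", "CT")
  dfs_tct <- build("dfs_tct", "DFS", "T+CT")
  dfs_ct <- build("dfs_ct", "DFS", "CT")
  if (!is.null(life_table)) {
    os_tct <- adjust_for_background_mortality(os_tct, life_table,
                                              age_weights)
    os_ct <- adjust_for_background_mortality(os_ct, life_table,
                                             age_weights)
  }
  list(os_tct = os_tct, os_ct = os_ct,
       dfs_tct = cap_dfs_at_os(dfs_tct, os_tct),
       dfs_ct = cap_dfs_at_os(dfs_ct, os_ct))
}

#' Run one full scenario over all cohorts
#'
#' Splits each cohort into trastuzumab-treated (T+CT curves and costs,
#' IV/SC by the year's formulation split) and untreated (CT curves and
#' costs) sub-cohorts according to the mode:
#' * `real_world`: the year's market share;
#' * `full_use`: share 1 (every patient treated — the ICER scenario);
#' * `ct_only`: share 0 (the hypothetical no-trastuzumab scenario).
#'
#' Results are additive over the split, so a real-world run is exactly
#' the share-weighted convex combination of the two pure runs.
#'
#' @param cohorts A [target_cohorts()] object.
#' @param curves Output of [prepare_efficacy_curves()].
#' @param shares A [market_share_series()] covering every cohort year.
#' @param cfg A `her2_config`.
#' @param mode `"real_world"`, `"full_use"` or `"ct_only"`.
#' @return A [scenario_result()] with cost categories
#'   `first_year_pharma`, `administration`, `monitoring`, `recurrence`.
#' @export
run_scenario <- function(cohorts, curves, shares, cfg,
                         mode = c("real_world", "full_use", "ct_only")) {
  mode <- match.arg(mode)
  ct_mult <- cfg$ct_cost_multiplier %||% 1
  unit_ct <- ct_backbone_cost(cfg)
  visits_ct <- weighted_iv_visits(cfg, with_trastuzumab = FALSE)
  visits_tct_iv <- weighted_iv_visits(cfg, with_trastuzumab = TRUE,
                                      formulation = "IV")
  pm <- cfg$progressed_mortality %||% NULL
  traces <- list(); streams <- list()

  add_subcohort <- function(n, y, treated, formulation = "IV") {
    if (n <= 0) return(invisible())
    os <- if (treated) curves$os_tct else curves$os_ct
    dfs <- if (treated) curves$dfs_tct else curves$dfs_ct
    tr <- build_cohort_trace(n, os, dfs, y, cfg$horizon_year,
                             discount_rate = cfg$discount_rate,
                             reference_year = cfg$reference_year,
                             discount_past = cfg$discount_past,
                             progression_method = cfg$progression_method,
                             cap_years = cfg$cap_years,
                             progressed_mortality = pm,
                             scenario = mode)
    visits <- if (!treated) visits_ct
              else if (formulation == "IV") visits_tct_iv else visits_ct
    cs <- rbind(
      first_year_pharma_costs(n, y, cfg,
                              treated_with_T = as.numeric(treated),
                              formulation = formulation,
                              ct_cost_multiplier = ct_mult,
                              unit_ct_cost = unit_ct),
      ancillary_costs(tr, NULL, cfg,
                      treated_with_T = as.numeric(treated),
                      n_iv_visits = visits, formulation = formulation))
    traces[[length(traces) + 1L]] <<- tr
    streams[[length(streams) + 1L]] <<- cs
    invisible()
  }

  for (i in seq_len(nrow(cohorts))) {
    y <- cohorts$cohort_year[i]
    n <- cohorts$target_n[i]
    sh <- switch(mode,
                 real_world = lookup_share(shares, y),
                 full_use = list(share = 1,
                                 sc_share = lookup_share(shares, y)$sc_share),
                 ct_only = list(share = 0, sc_share = 0))
    n_tr <- n * sh$share
    add_subcohort(n_tr * (1 - sh$sc_share), y, treated = TRUE, "IV")
    add_subcohort(n_tr * sh$sc_share, y, treated = TRUE, "SC")
    add_subcohort(n * (1 - sh$share), y, treated = FALSE)
  }
  aggregate_traces(traces, streams, label = mode)
}

#' Incremental cost-effectiveness ratios between two scenarios
#'
#' Computes incremental cost over incremental (disease-free) life years.
#' A non-positive incremental effect is flagged as a dominance case and
#' no ratio is reported.  Ratios are also reported rounded to the
#' nearest euro for display; internal arithmetic is unrounded.
#'
#' @param a,b [scenario_result()] objects (intervention and comparator)
#'   computed under the same horizon and discounting.
#' @return A list of class `icer_result` with `inc_cost`, `inc_ly`,
#'   `inc_dfly`, `icer_ly`, `icer_dfly`, rounded twins `icer_ly_eur`,
#'   `icer_dfly_eur`, and `dominance`.
#' @export
compute_icer <- function(a, b) {
  inc <- scenario_diff(a, b)
  dominance <- !is.finite(inc$inc_ly) || inc$inc_ly <= 0
  icer_ly <- if (dominance) NA_real_ else inc$inc_cost / inc$inc_ly
  icer_dfly <- if (!is.finite(inc$inc_dfly) || inc$inc_dfly <= 0)
    NA_real_ else inc$inc_cost / inc$inc_dfly
  structure(list(inc_cost = inc$inc_cost, inc_ly = inc$inc_ly,
                 inc_dfly = inc$inc_dfly,
                 icer_ly = icer_ly, icer_dfly = icer_dfly,
                 icer_ly_eur = round(icer_ly),
                 icer_dfly_eur = round(icer_dfly),
                 dominance = dominance),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  if (x$dominance) {
    cat("Dominance case: incremental effect <= 0; no ICER reported\n")
    cat(sprintf("  incremental cost EUR %.0f\n", x$inc_cost))
  } else {
    cat(sprintf("ICER: EUR %.0f per LY gained, EUR %.0f per DFLY gained\n",
                x$icer_ly_eur, x$icer_dfly_eur))
    cat(sprintf("  incremental cost EUR %.0f over %.0f LYG (%.0f DFLYG)\n",
                x$inc_cost, x$inc_ly, x$inc_dfly))
  }
  invisible(x)
}

#' Run the full pipeline: curves, three scenarios, increments, ICER
#'
#' Prepares the efficacy curves, runs the chemotherapy-only, real-world
#' and full-use scenarios, and derives the real-world increment (the
#' headline LYG/DFLYG and incremental cost) and the full-use ICER, plus
#' the general-population comparator when a life table is supplied.
#'
#' @param inputs List with `cohorts` (a [target_cohorts()]), `km` (see
#'   [prepare_efficacy_curves()]), optional `life_table`, `age_weights`
#'   and `alt_efficacy` (named list of alternative `km` input sets for
#'   sensitivity analyses).
#' @param cfg A `her2_config`.
#' @return A list of class `her2_model_run` with elements `curves`,
#'   `real_world`, `ct_only`, `full_use`, `increment` (real-world vs
#'   CT-only), `icer` (full-use vs CT-only), `general_population_ly`.
#' @export
run_full_model <- function(inputs, cfg) {
  validate_config(cfg)
  cohorts <- inputs$cohorts
  curves <- prepare_efficacy_curves(inputs$km, cfg, inputs$life_table,
                                    inputs$age_weights)
  shares <- cfg$market_shares
  ct <- run_scenario(cohorts, curves, shares, cfg, "ct_only")
  rw <- run_scenario(cohorts, curves, shares, cfg, "real_world")
  fu <- run_scenario(cohorts, curves, shares, cfg, "full_use")
  gp <- if (!is.null(inputs$life_table))
    general_population_ly(cohorts, inputs$life_table, cfg$horizon_year,
                          rate = cfg$discount_rate,
                          reference_year = cfg$reference_year,
                          discount_past = cfg$discount_past,
                          age_weights = inputs$age_weights)
  else NA_real_
  structure(list(curves = curves, real_world = rw, ct_only = ct,
                 full_use = fu,
                 increment = scenario_diff(rw, ct),
                 icer = compute_icer(fu, ct),
                 general_population_ly = as.numeric(gp)),
            class = "her2_model_run")
}

#' @export
print.her2_model_run <- function(x, ...) {
  cat("Full model run\n")
  cat(sprintf("  real-world LYG %.0f, DFLYG %.0f, incremental cost EUR %.0f\n",
              x$increment$inc_ly, x$increment$inc_dfly,
              x$increment$inc_cost))
  if (!x$icer$dominance)
    cat(sprintf("  full-use ICER EUR %.0f /LYG, EUR %.0f /DFLYG\n",
                x$icer$icer_ly_eur, x$icer$icer_dfly_eur))
  if (is.finite(x$general_population_ly))
    cat(sprintf("  general-population comparator: %.0f LY\n",
                x$general_population_ly))
  invisible(x)
}

## knobs a sensitivity scenario may override
sa_knobs <- c("horizon_year", "discount_rate", "switch_time",
              "progression_method", "cap_years", "recurrence_cost",
              "admin_visit_cost", "echo_cost", "ct_cost_multiplier",
              "efficacy")

#' Default deterministic sensitivity scenarios
#'
#' The battery of one-way scenarios: truncated horizon, alternative
#' efficacy source slot, parametric curves from the start, Markov
#' progression accounting, removal of the 7-year recurrence cap,
#' discount rates 0% and 5%, +/-25% on the administration and
#' echocardiogram unit costs and on the chemotherapy cost, and the
#' recurrence-cost range endpoints.
#'
#' @param cfg The base configuration (supplies the range endpoints).
#' @return Named list of scenarios (each a list of overrides).
#' @export
default_sensitivity_scenarios <- function(cfg) {
  list(
    horizon_2030 = list(horizon_year = 2030),
    efficacy_alternative = list(efficacy = "alternative"),
    parametric_from_start = list(switch_time = 0),
    markov_progressions = list(progression_method = "Markov"),
    relapses_beyond_7y = list(cap_years = cfg$horizon_year -
                                min(cfg$cohort_years)),
    discount_0 = list(discount_rate = 0),
    discount_5 = list(discount_rate = 0.05),
    admin_echo_minus25 = list(admin_visit_cost = cfg$admin_visit_cost * 0.75,
                              echo_cost = cfg$echo_cost * 0.75),
    admin_echo_plus25 = list(admin_visit_cost = cfg$admin_visit_cost * 1.25,
                             echo_cost = cfg$echo_cost * 1.25),
    ct_cost_minus25 = list(ct_cost_multiplier = 0.75),
    ct_cost_plus25 = list(ct_cost_multiplier = 1.25),
    recurrence_cost_low = list(recurrence_cost = cfg$recurrence_cost_range[1L]),
    recurrence_cost_high = list(recurrence_cost = cfg$recurrence_cost_range[2L])
  )
}

#' Deterministic sensitivity analysis
#'
#' Re-runs the full pipeline once per scenario, each scenario overriding
#' a declared subset of configuration knobs, and tabulates the
#' real-world incremental results next to the base case.  A scenario
#' requesting an alternative efficacy source that is not present in
#' `inputs$alt_efficacy` is skipped with a warning.
#'
#' @inheritParams run_full_model
#' @param scenarios Named list of override lists (default
#'   [default_sensitivity_scenarios()]).
#' @return `data.frame` with columns `scenario`, `lyg`, `dflyg`,
#'   `inc_cost`.
#' @export
run_sensitivity <- function(inputs, cfg,
                            scenarios = default_sensitivity_scenarios(cfg)) {
  base <- run_full_model(inputs, cfg)
  rows <- list(data.frame(scenario = "base_case",
                          lyg = base$increment$inc_ly,
                          dflyg = base$increment$inc_dfly,
                          inc_cost = base$increment$inc_cost))
  for (nm in names(scenarios)) {
    ov <- scenarios[[nm]]
    bad <- setdiff(names(ov), sa_knobs)
    if (length(bad))
      stop_her2("scenario '", nm, "' overrides undeclared knob(s): ",
                paste(bad, collapse = ", "))
    inp <- inputs
    cfg_i <- cfg
    if (!is.null(ov$efficacy)) {
      alt <- inputs$alt_efficacy[[ov$efficacy]]
      if (is.null(alt)) {
        warning("scenario '", nm, "': efficacy source '", ov$efficacy,
                "' not supplied; skipped", call. = FALSE)
        next
      }
      inp$km <- alt
      ov$efficacy <- NULL
    }
    for (k in names(ov)) cfg_i[[k]] <- ov[[k]]
    run <- run_full_model(inp, cfg_i)
    rows[[length(rows) + 1L]] <-
      data.frame(scenario = nm, lyg = run$increment$inc_ly,
                 dflyg = run$increment$inc_dfly,
                 inc_cost = run$increment$inc_cost)
  }
  do.call(rbind, rows)
}
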
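## Direct healthcare costs: regimen dosing schedules, per-vial drug
## pricing, statutory price deductions by year and formulation, CPI
## adjustment, day-hospital administration, echocardiogram monitoring
## and the one-off recurrence cost.

#' Build a regimen component
#'
#' @param drug Drug name (must match the price table for costing).
#' @param rule Dosing rule: `"per_kg"`, `"per_m2"` or `"flat"`.
#' @param dose Dose per administration, in mg/kg, mg/m2 or mg.
#' @param cycle_weeks Weeks between administrations.
#' @param n_cycles Number of administrations (>= 1).
#' @param start_week Week of the first administration.
#' @param loading_dose Optional different dose for the first
#'   administration (same rule).
#' @param route `"IV"` or `"SC"`.
#' @return A list describing the component.
#' @export
regimen_component <- function(drug, rule = c("per_m2", "per_kg", "flat"),
                              dose, cycle_weeks, n_cycles,
                              start_week = 0, loading_dose = NULL,
                              route = "IV") {
  rule <- match.arg(rule)
  check_number(dose, "dose", lower = 0, strict_lower = TRUE)
  check_number(n_cycles, "n_cycles", lower = 1)
  list(drug = drug, rule = rule, dose = dose, cycle_weeks = cycle_weeks,
       n_cycles = as.integer(n_cycles), start_week = start_week,
       loading_dose = loading_dose, route = route)
}

#' Regimen specification
#' @param name Regimen label.
#' @param components List of [regimen_component()]s.
#' @param route Dominant route of the regimen (for deduction lookup).
#' @return A list of class `regimen_spec`.
#' @export
regimen_spec <- function(name, components, route = "IV") {
  structure(list(name = name, components = components, route = route),
            class = "regimen_spec")
}

#' One year of IV trastuzumab
#'
#' 8 mg/kg loading dose followed by 6 mg/kg every 3 weeks for one year:
#' 18 administrations at weeks 0, 3, ..., 51.
#' @return A [regimen_spec()].
#' @export
regimen_trastuzumab_iv <- function() {
  regimen_spec("trastuzumab IV",
               list(regimen_component("trastuzumab_iv", "per_kg", dose = 6,
                                      cycle_weeks = 3, n_cycles = 18,
                                      loading_dose = 8, route = "IV")),
               route = "IV")
}

#' One year of SC trastuzumab
#'
#' 600 mg flat every 3 weeks for one year: 18 administrations.
#' @return A [regimen_spec()].
#' @export
regimen_trastuzumab_sc <- function() {
  regimen_spec("trastuzumab SC",
               list(regimen_component("trastuzumab_sc", "flat", dose = 600,
                                      cycle_weeks = 3, n_cycles = 18,
                                      route = "SC")),
               route = "SC")
}

#' AC-T chemotherapy backbone
#'
#' Doxorubicin 60 mg/m2 for 4 cycles plus cyclophosphamide 600 mg/m2
#' for 6 cycles (3-weekly), followed by a taxane: weekly paclitaxel
#' 80 mg/m2 for 12 weeks, or 3-weekly docetaxel (representative
#' 100 mg/m2 x 4; the docetaxel dose in this scheme is a configurable
#' default, not a published constant).
#'
#' @param taxane `"paclitaxel"` or `"docetaxel"`.
#' @return A [regimen_spec()].
#' @export
regimen_act <- function(taxane = c("paclitaxel", "docetaxel")) {
  taxane <- match.arg(taxane)
  tax <- if (taxane == "paclitaxel")
    regimen_component("paclitaxel", "per_m2", dose = 80, cycle_weeks = 1,
                      n_cycles = 12, start_week = 18)
  else
    regimen_component("docetaxel", "per_m2", dose = 100, cycle_weeks = 3,
                      n_cycles = 4, start_week = 18)
  regimen_spec(paste0("AC-T (", taxane, ")"),
               list(regimen_component("doxorubicin", "per_m2", dose = 60,
                                      cycle_weeks = 3, n_cycles = 4),
                    regimen_component("cyclophosphamide", "per_m2",
                                      dose = 600, cycle_weeks = 3,
                                      n_cycles = 6),
                    tax))
}

#' TC chemotherapy backbone
#'
#' Carboplatin plus a taxane, 4 3-weekly cycles.  Component doses
#' (docetaxel 75 mg/m2, carboplatin 630 mg flat) are representative
#' configurable defaults, not published constants; the chemotherapy
#' backbone cancels out of all incremental results.
#'
#' @param taxane `"docetaxel"` or `"paclitaxel"`.
#' @return A [regimen_spec()].
#' @export
regimen_tc <- function(taxane = c("docetaxel", "paclitaxel")) {
  taxane <- match.arg(taxane)
  tax <- if (taxane == "docetaxel")
    regimen_component("docetaxel", "per_m2", dose = 75, cycle_weeks = 3,
                      n_cycles = 4)
  else
    regimen_component("paclitaxel", "per_m2", dose = 80, cycle_weeks = 1,
                      n_cycles = 12)
  regimen_spec(paste0("TC (", taxane, ")"),
               list(regimen_component("carboplatin", "flat", dose = 630,
                                      cycle_weeks = 3, n_cycles = 4),
                    tax))
}

#' Administrations of a regimen over the first year
#'
#' Expands a regimen into its individual administrations, converting
#' per-kg and per-m2 doses to mg with the configured mean body weight
#' and body surface (66.4 kg and 1.73 m2 by default).
#'
#' @param regimen A [regimen_spec()].
#' @param weight_kg Mean body weight for per-kg dosing.
#' @param bsa_m2 Mean body surface for per-m2 dosing.
#' @return `data.frame` with columns `week`, `drug`, `mg`, `route`.
#' @export
doses_in_first_year <- function(regimen, weight_kg = 66.4, bsa_m2 = 1.73) {
  stopifnot(inherits(regimen, "regimen_spec"))
  rows <- lapply(regimen$components, function(cmp) {
    weeks <- cmp$start_week + cmp$cycle_weeks * (seq_len(cmp$n_cycles) - 1)
    factor <- switch(cmp$rule, per_kg = weight_kg, per_m2 = bsa_m2,
                     flat = 1)
    mg <- rep(cmp$dose * factor, cmp$n_cycles)
    if (!is.null(cmp$loading_dose)) mg[1L] <- cmp$loading_dose * factor
    data.frame(week = weeks, drug = cmp$drug, mg = mg, route = cmp$route)
  })
  out <- do.call(rbind, rows)
  out[order(out$week, out$drug), , drop = FALSE]
}

#' Cost of a dose list under a vial policy
#'
#' `whole_vials` (default): each administration consumes
#' `ceiling(mg / vial_mg)` whole vials at the per-vial price (no vial
#' sharing); `exact_mg`: linear pricing by milligram.
#'
#' @param doses Output of [doses_in_first_year()].
#' @param prices Price table `data.frame(drug, vial_mg, price)`.
#' @param vial_policy `"whole_vials"` or `"exact_mg"`.
#' @return Total cost in EUR, with attribute `vial_policy`.
#' @export
drug_cost <- function(doses, prices,
                      vial_policy = c("whole_vials", "exact_mg")) {
  vial_policy <- match.arg(vial_policy)
  if (nrow(doses) == 0L)
    return(structure(0, vial_policy = vial_policy))
  i <- match(doses$drug, prices$drug)
  if (any(is.na(i)))
    stop_her2("no price for drug(s): ",
              paste(unique(doses$drug[is.na(i)]), collapse = ", "))
  per_admin <- if (vial_policy == "whole_vials")
    ceiling(doses$mg / prices$vial_mg[i]) * prices$price[i]
  else
    doses$mg / prices$vial_mg[i] * prices$price[i]
  structure(sum(per_admin), vial_policy = vial_policy)
}

#' Apply the statutory price deduction
#'
#' Multiplies a cost by `1 - rate(year, formulation)` according to the
#' deduction schedule (see [default_deduction_schedule()]).
#'
#' @param cost Cost in EUR.
#' @param year Cohort calendar year.
#' @param formulation `"IV"` or `"SC"`.
#' @param schedule Deduction schedule `data.frame(formulation,
#'   year_from, year_to, rate)`.
#' @return The deducted cost.
#' @export
apply_deduction <- function(cost, year, formulation = c("IV", "SC"),
                            schedule = default_deduction_schedule()) {
  formulation <- match.arg(formulation)
  cost * (1 - deduction_rate(year, formulation, schedule))
}

#' Deduction rate for a year and formulation
#' @inheritParams apply_deduction
#' @return The deduction proportion.
#' @export
deduction_rate <- function(year, formulation = c("IV", "SC"),
                           schedule = default_deduction_schedule()) {
  formulation <- match.arg(formulation)
  hit <- schedule$formulation == formulation &
    schedule$year_from <= year & year <= schedule$year_to
  if (!any(hit))
    stop_her2(sprintf("no deduction rule for %s in year %d",
                      formulation, year))
  schedule$rate[which(hit)[1L]]
}

#' Mix-weighted chemotherapy backbone cost per patient
#'
#' First-year chemotherapy drug cost weighted over the TC / AC-T scheme
#' mix and the taxane split within each scheme, at current prices for
#' every cohort.
#'
#' @param cfg A `her2_config`.
#' @param vial_policy Passed to [drug_cost()].
#' @return Cost in EUR per patient.
#' @export
ct_backbone_cost <- function(cfg, vial_policy = "whole_vials") {
  w <- cfg$mean_weight_kg; b <- cfg$body_surface_m2
  cost_of <- function(reg) as.numeric(
    drug_cost(doses_in_first_year(reg, w, b), cfg$prices, vial_policy))
  act <- cfg$taxane_split[["primary"]] * cost_of(regimen_act("paclitaxel")) +
    cfg$taxane_split[["secondary"]] * cost_of(regimen_act("docetaxel"))
  tc <- cfg$taxane_split[["primary"]] * cost_of(regimen_tc("docetaxel")) +
    cfg$taxane_split[["secondary"]] * cost_of(regimen_tc("paclitaxel"))
  cfg$regimen_mix[["ACT"]] * act + cfg$regimen_mix[["TC"]] * tc
}

#' Deducted trastuzumab cost per patient for a cohort year
#'
#' One year of trastuzumab at the configured prices and dosing
#' constants, with the statutory deduction of the cohort year applied.
#'
#' @param cfg A `her2_config`.
#' @param year Cohort calendar year.
#' @param formulation `"IV"` or `"SC"`.
#' @param vial_policy Passed to [drug_cost()].
#' @return Cost in EUR per patient.
#' @export
trastuzumab_cost <- function(cfg, year, formulation = c("IV", "SC"),
                             vial_policy = "whole_vials") {
  formulation <- match.arg(formulation)
  reg <- if (formulation == "IV") regimen_trastuzumab_iv()
         else regimen_trastuzumab_sc()
  raw <- drug_cost(doses_in_first_year(reg, cfg$mean_weight_kg,
                                       cfg$body_surface_m2),
                   cfg$prices, vial_policy)
  apply_deduction(as.numeric(raw), year, formulation,
                  cfg$deduction_schedule)
}

#' Day-hospital visits implied by a set of regimens
#'
#' Number of distinct weeks with at least one IV administration across
#' the given regimens — co-administered IV drugs share a single
#' day-hospital visit; SC administrations generate none.
#'
#' @param regimens A [regimen_spec()] or list of them.
#' @return Integer visit count.
#' @export
iv_visits <- function(regimens) {
  if (inherits(regimens, "regimen_spec")) regimens <- list(regimens)
  weeks <- unlist(lapply(regimens, function(r) {
    d <- doses_in_first_year(r)
    d$week[d$route == "IV"]
  }))
  length(unique(weeks))
}

## Mix-weighted IV visit counts for the two arms.
## with_trastuzumab: visits of CT + IV trastuzumab union (or CT only
## when the patient is on the SC formulation).
weighted_iv_visits <- function(cfg, with_trastuzumab = FALSE,
                               formulation = "IV") {
  trast <- if (with_trastuzumab && formulation == "IV")
    list(regimen_trastuzumab_iv()) else list()
  variants <- list(
    list(w = cfg$regimen_mix[["ACT"]] * cfg$taxane_split[["primary"]],
         reg = regimen_act("paclitaxel")),
    list(w = cfg$regimen_mix[["ACT"]] * cfg$taxane_split[["secondary"]],
         reg = regimen_act("docetaxel")),
    list(w = cfg$regimen_mix[["TC"]] * cfg$taxane_split[["primary"]],
         reg = regimen_tc("docetaxel")),
    list(w = cfg$regimen_mix[["TC"]] * cfg$taxane_split[["secondary"]],
         reg = regimen_tc("paclitaxel")))
  sum(vapply(variants, function(v)
    v$w * iv_visits(c(list(v$reg), trast)), numeric(1)))
}

#' Administration, monitoring and recurrence costs of a cohort trace
#'
#' Builds the non-pharmacy cost stream of one (sub)cohort:
#' * administration: IV day-hospital visits of the first-year regimen at
#'   the configured unit cost, CPI-adjusted to the cohort year and
#'   charged there;
#' * monitoring: for trastuzumab-treated patients only, the configured
#'   number of echocardiograms in the treatment year plus one per year
#'   among disease-free survivors thereafter, CPI-adjusted;
#' * recurrence: each expected new progression incurs the one-off
#'   recurrence cost in the calendar year of progression.
#'
#' Costs are discounted with the configuration's rate and reference
#' year.
#'
#' @param trace A [build_cohort_trace()] result.
#' @param progression A [progression_series()] aligned with the trace
#'   (defaults to the trace's own `new_progressions` column).
#' @param cfg A `her2_config`.
#' @param treated_with_T Proportion of the trace cohort treated with
#'   trastuzumab (0 or 1 for pure sub-cohorts).
#' @param n_iv_visits First-year day-hospital visits per patient
#'   (default: mix-weighted count implied by the configured regimens,
#'   with IV trastuzumab when `treated_with_T > 0`).
#' @param formulation Trastuzumab formulation of the treated patients.
#' @return `data.frame` with columns `cohort_year`, `calendar_year`,
#'   `category`, `cost`, `cost_disc`.
#' @export
ancillary_costs <- function(trace, progression = NULL, cfg,
                            treated_with_T = 1, n_iv_visits = NULL,
                            formulation = "IV") {
  check_proportion(treated_with_T, "treated_with_T")
  if (nrow(trace) == 0L)
    return(data.frame(cohort_year = integer(0), calendar_year = integer(0),
                      category = character(0), cost = numeric(0),
                      cost_disc = numeric(0)))
  n0 <- attr(trace, "n0")
  y0 <- trace$cohort_year[1L]
  if (is.null(n_iv_visits))
    n_iv_visits <- weighted_iv_visits(cfg, treated_with_T > 0, formulation)
  newp <- if (is.null(progression)) trace$new_progressions
          else progression$new_progressions[seq_len(nrow(trace))]
  cpi_y <- cpi_factor(trace$calendar_year, cfg)
  miss <- !is.finite(cpi_y)
  if (any(miss))
    stop_her2("CPI index missing for year(s) ",
              paste(trace$calendar_year[miss], collapse = ", "))

  admin <- numeric(nrow(trace))
  admin[1L] <- n0 * n_iv_visits * cfg$admin_visit_cost * cpi_y[1L]

  echo <- numeric(nrow(trace))
  if (treated_with_T > 0 && nrow(trace) > 0) {
    echo[1L] <- treated_with_T * n0 * cfg$echo_treatment_year *
      cfg$echo_cost * cpi_y[1L]
    if (nrow(trace) > 1L) {
      t2 <- 2:nrow(trace)
      echo[t2] <- treated_with_T * trace$disease_free[t2] *
        cfg$echo_cost * cpi_y[t2]
    }
  }

  recur <- newp * cfg$recurrence_cost

  long <- rbind(
    data.frame(calendar_year = trace$calendar_year,
               category = "administration", cost = admin),
    data.frame(calendar_year = trace$calendar_year,
               category = "monitoring", cost = echo),
    data.frame(calendar_year = trace$calendar_year,
               category = "recurrence", cost = recur))
  long$cohort_year <- y0
  long$cost_disc <- discount(long$cost, long$calendar_year,
                             cfg$discount_rate, cfg$reference_year,
                             cfg$discount_past)
  long[, c("cohort_year", "calendar_year", "category", "cost",
           "cost_disc")]
}

#' First-year pharmacy cost stream of a (sub)cohort
#'
#' Chemotherapy backbone for every patient plus deducted trastuzumab for
#' the treated, charged wholly in the cohort year and discounted.
#'
#' @param n0 Sub-cohort size.
#' @param cohort_year Cohort calendar year.
#' @param cfg A `her2_config`.
#' @param treated_with_T Proportion treated with trastuzumab.
#' @param formulation Trastuzumab formulation.
#' @param ct_cost_multiplier Multiplier on the chemotherapy backbone
#'   cost (sensitivity analyses).
#' @param unit_ct_cost Precomputed backbone cost per patient (optional,
#'   avoids recomputation in loops).
#' @return One-row cost-stream `data.frame`.
#' @export
first_year_pharma_costs <- function(n0, cohort_year, cfg,
                                    treated_with_T = 1,
                                    formulation = "IV",
                                    ct_cost_multiplier = 1,
                                    unit_ct_cost = NULL) {
  ct <- (unit_ct_cost %||% ct_backbone_cost(cfg)) * ct_cost_multiplier
  tr <- if (treated_with_T > 0)
    trastuzumab_cost(cfg, cohort_year, formulation) else 0
  cost <- n0 * (ct + treated_with_T * tr)
  data.frame(cohort_year = cohort_year, calendar_year = cohort_year,
             category = "first_year_pharma", cost = cost,
             cost_disc = discount(cost, cohort_year, cfg$discount_rate,
                                  cfg$reference_year, cfg$discount_past))
}
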
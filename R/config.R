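## Model configuration: every constant of the base-case analysis
## (filters, prices, dosing, deduction and CPI schedules, discount rate,
## horizon, market shares) in one validated list, plus the published
## reference aggregates used for arithmetic cross-checks.

#' Default model configuration
#'
#' Returns the full base-case configuration of the analysis, ready for
#' the end-to-end pipeline:
#' * cohorts 2006-2017 followed to 2035, discounted at 3% per year from
#'   the 2017 reference year onwards (earlier calendar years are not
#'   discounted);
#' * target-population filters: 18% ductal carcinoma in situ and 7%
#'   de-novo metastatic exclusions, HER2+ prevalence 16.7% per year
#'   (override per year via `her2_prevalence`);
#' * effectiveness handling: empirical curve kept to `switch_time = 10`
#'   years then Weibull tail; recurrences capped at 7 years since
#'   diagnosis; partitioned-survival progression accounting in the base
#'   case;
#' * costs: mean dosing weight 66.4 kg and body surface 1.73 m2, day
#'   hospital administration 211.64 EUR and echocardiogram 133 EUR per
#'   unit (CPI-adjusted per cohort year), one-off recurrence cost
#'   183,170 EUR (mean of the 157,658-208,682 EUR range), statutory
#'   price deductions of 0% / 7.5% / 15% for IV trastuzumab by period
#'   and 7.5% for SC;
#' * management mix: TC vs AC-T 25:75, with a 75:25 taxane split in each
#'   scheme; trastuzumab market share rising linearly from 40% in 2006
#'   to 100% in 2014 and holding, SC formulation available from 2015.
#'
#' Drug prices ship as representative per-vial defaults (actual hospital
#' dispensation prices are confidential); chemotherapy backbone costs
#' cancel out of incremental results, and every price can be overridden.
#'
#' @return A list of class `her2_config`.
#' @export
make_default_config <- function() {
  cfg <- list(
    cohort_years    = 2006:2017,
    horizon_year    = 2035,
    reference_year  = 2017,
    discount_rate   = 0.03,
    discount_past   = FALSE,
    gender          = "F",
    age_range       = c(25, 90),
    dcis_frac       = 0.18,
    metastatic_frac = 0.07,
    her2_prevalence = data.frame(year = 2006:2017, prevalence = 0.167),
    testing_uptake  = 1.0,

    switch_time        = 10,
    cap_years          = 7,
    progression_method = "PSM",

    mean_weight_kg = 66.4,
    body_surface_m2 = 1.73,
    admin_visit_cost = 211.64,
    echo_cost = 133,
    echo_treatment_year = 4,
    recurrence_cost = 183170,
    recurrence_cost_range = c(157658, 208682),

    regimen_mix  = c(ACT = 0.75, TC = 0.25),
    taxane_split = c(primary = 0.75, secondary = 0.25),

    prices = default_price_table(),
    deduction_schedule = default_deduction_schedule(),
    cpi = default_cpi_series(),
    market_shares = default_market_shares()
  )
  class(cfg) <- "her2_config"
  validate_config(cfg)
}

#' Validate a model configuration
#' @param cfg A configuration list (class `her2_config`).
#' @return The configuration, invisibly checked.
#' @export
validate_config <- function(cfg) {
  check_proportion(cfg$dcis_frac, "dcis_frac")
  check_proportion(cfg$metastatic_frac, "metastatic_frac")
  check_proportion(cfg$her2_prevalence$prevalence, "her2_prevalence")
  check_number(cfg$discount_rate, "discount_rate", lower = 0)
  check_number(cfg$horizon_year, "horizon_year",
               lower = max(cfg$cohort_years))
  check_number(cfg$cap_years, "cap_years", lower = 0)
  check_number(cfg$switch_time, "switch_time", lower = 0)
  if (abs(sum(cfg$regimen_mix) - 1) > 1e-9)
    stop_her2("regimen_mix must sum to 1")
  if (abs(sum(cfg$taxane_split) - 1) > 1e-9)
    stop_her2("taxane_split must sum to 1")
  if (any(cfg$prices$price < 0)) stop_her2("prices must be >= 0")
  check_proportion(cfg$market_shares$share, "market share")
  check_proportion(cfg$market_shares$sc_share, "SC share")
  if (any(cfg$market_shares$sc_share[cfg$market_shares$year < 2015] > 0))
    stop_her2("SC formulation share must be 0 before 2015")
  invisible(cfg)
}

#' Default per-vial price table
#'
#' Representative per-vial dispensation prices (EUR).  The trastuzumab
#' vial sizes (150 mg IV, 600 mg SC) are the marketed presentations; the
#' chemotherapy prices are synthetic placeholders, documented as such —
#' the chemotherapy backbone is identical in both scenarios and cancels
#' out of every incremental result.
#'
#' @return `data.frame` with columns `drug`, `vial_mg`, `price`.
#' @export
default_price_table <- function() {
  data.frame(
    drug = c("trastuzumab_iv", "trastuzumab_sc", "paclitaxel",
             "docetaxel", "doxorubicin", "cyclophosphamide", "carboplatin"),
    vial_mg = c(150, 600, 100, 80, 50, 1000, 450),
    price = c(595, 1580, 35, 28, 18, 12, 30)
  )
}

#' Default statutory deduction schedule
#'
#' Price deduction applied to trastuzumab by cohort year and
#' formulation: no deduction for IV before 2010, 7.5% for 2010-2013, 15%
#' from 2014 onwards; 7.5% for the SC formulation since its marketing.
#'
#' @return `data.frame` with columns `formulation`, `year_from`,
#'   `year_to`, `rate`.
#' @export
default_deduction_schedule <- function() {
  data.frame(
    formulation = c("IV", "IV", "IV", "SC", "SC"),
    year_from = c(-Inf, 2010, 2014, -Inf, 2014),
    year_to   = c(2009, 2013,  Inf, 2013,  Inf),
    rate      = c(0, 0.075, 0.15, 0, 0.075)
  )
}

#' Default consumer-price-index series
#'
#' Index normalized to 1 in the 2017 reference year, backcast at a
#' constant 1.5% annual inflation — a synthetic stand-in for the
#' national CPI series used to bring the administration and monitoring
#' unit costs to each cohort's price level.  Years beyond the series are
#' held at the closest available value.
#'
#' @param years Calendar years covered.
#' @param annual_inflation Constant annual rate used to build the index.
#' @param reference_year Year at which the index equals 1.
#' @return `data.frame` with columns `year`, `index`.
#' @export
default_cpi_series <- function(years = 2006:2017, annual_inflation = 0.015,
                               reference_year = 2017) {
  data.frame(year = years,
             index = (1 + annual_inflation)^(years - reference_year))
}

#' CPI adjustment factor for a calendar year
#'
#' Ratio of the CPI index in `year` to the index in the reference year;
#' years outside the series are clamped to its ends.
#'
#' @param year Calendar year(s).
#' @param cfg A `her2_config` (uses `cfg$cpi` and `cfg$reference_year`).
#' @return Numeric factor(s).
#' @export
cpi_factor <- function(year, cfg) {
  cpi <- cfg$cpi
  y <- pmin(pmax(year, min(cpi$year)), max(cpi$year))
  ref <- pmin(pmax(cfg$reference_year, min(cpi$year)), max(cpi$year))
  cpi$index[match(y, cpi$year)] / cpi$index[match(ref, cpi$year)]
}

#' Default trastuzumab market-share series
#'
#' Share of eligible patients actually receiving adjuvant trastuzumab by
#' cohort year: linear from 40% in 2006 to 100% in 2014, holding at 100%
#' thereafter.  `sc_share` is the fraction of treated patients on the
#' subcutaneous formulation (0 before its 2015 availability, then an
#' assumed uptake).  The series is configuration data, not code, and can
#' be replaced wholesale.
#'
#' @param years Cohort years covered.
#' @return A [market_share_series()] data frame.
#' @export
default_market_shares <- function(years = 2006:2017) {
  share <- pmin(0.40 + 0.60 * (years - 2006) / 8, 1)
  sc <- ifelse(years >= 2015, pmin(0.30 + 0.10 * (years - 2015), 1), 0)
  market_share_series(years, share, sc)
}

#' Published reference aggregates
#'
#' The reported national-level aggregates of the Spanish adjuvant
#' trastuzumab burden analysis that this package models: per-year target
#' cohort sizes (2006-2017), scenario life-year and cost totals under
#' real-world market shares and under full trastuzumab use, the
#' general-population comparator and headline per-patient figures.
#' These printed values serve as *inputs* to the aggregation and ICER
#' operations for arithmetic cross-checks; they are not recomputed from
#' the unpublished patient-level sources.
#'
#' @return A nested list; see the elements' names.
#' @export
reference_estimates <- function() {
  list(
    cohort_years = 2006:2017,
    total_bc_cases = c(21132, 21608, 22101, 22533, 22925, 23291,
                       23651, 23936, 24175, 24442, 24724, 24994),
    target_by_year = c(2664, 2724, 2787, 2841, 2891, 2937,
                       2982, 3018, 3249, 3377, 3173, 3208),
    n_total = 35851,
    real_world = list(ly_tct = 605358, dfly_tct = 525964,
                      ly_ct = 564137, dfly_ct = 489916),
    full_use = list(cost_tct = 1581553536, cost_ct = 503587698,
                    ly_tct = 616354, ly_ct = 564137,
                    dfly_tct = 534907, dfly_ct = 489916),
    general_population_ly = 704331,
    incremental_cost_eur = 880.43e6,
    ct_total_cost_eur = 503.59e6
  )
}

#' Write a configuration as a structured text file
#'
#' Serializes the configuration (nested key-value sections, tables as
#' CSV-like blocks) to YAML so a run can be archived and re-read.
#'
#' @param cfg A `her2_config`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  ser <- lapply(unclass(cfg), function(x) {
    if (is.data.frame(x)) lapply(as.list(x), function(col) unname(col)) else x
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}
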
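## Incidence modelling: Poisson regression of counts on age band and
## calendar year with population exposure, projection of annual new
## cases, and filtering to the treated-candidate HER2+ early-BC target
## population.

#' Fit a Poisson log-linear incidence model
#'
#' Maximum-likelihood Poisson regression of case counts on age band
#' (factor) and calendar year (linear), with the log person-years as
#' exposure offset — the standard model for projecting cancer incidence
#' rates by age and period.
#'
#' @param data An incidence table: `data.frame` with columns `year`,
#'   `age_band`, `cases`, `population` (and optionally `gender`, fitted
#'   as a factor when it varies).
#' @return A list of class `incidence_model` with elements `fit` (the
#'   `glm` object), `coefficients` and `deviance`.
#' @export
fit_incidence_model <- function(data) {
  data <- as.data.frame(data)
  req <- c("year", "age_band", "cases", "population")
  if (!all(req %in% names(data)))
    stop_her2("incidence data needs columns ",
              paste(req, collapse = ", "))
  if (any(data$population <= 0))
    stop_her2("all populations must be > 0")
  if (any(data$cases < 0)) stop_her2("case counts must be >= 0")
  if (length(unique(data$year)) < 2L)
    stop_her2("need >= 2 distinct years to identify the year trend")
  if (length(unique(data$age_band)) < 2L)
    stop_her2("need >= 2 age bands to identify age effects")
  data$age_band <- factor(data$age_band)
  has_gender <- "gender" %in% names(data) &&
    length(unique(data$gender)) > 1L
  fml <- if (has_gender) cases ~ age_band + gender + year
         else cases ~ age_band + year
  fit <- glm(fml, family = poisson(), data = data,
             offset = log(population))
  if (!fit$converged)
    stop_her2("Poisson incidence fit did not converge")
  if (any(is.na(coef(fit))))
    stop_her2("degenerate design: some coefficients are not estimable ",
              "(aliased columns - check that age bands and years vary ",
              "independently)")
  structure(list(fit = fit, coefficients = coef(fit),
                 deviance = fit$deviance), class = "incidence_model")
}

#' @export
print.incidence_model <- function(x, ...) {
  cat("Poisson incidence model (log-linear in age band and year)\n")
  cat(sprintf("  year effect: %.5f (log-rate per calendar year)\n",
              x$coefficients[["year"]]))
  cat(sprintf("  residual deviance: %.2f\n", x$deviance))
  invisible(x)
}

#' Predicted incidence rate per person-year
#'
#' @param model An [fit_incidence_model()] result.
#' @param newdata `data.frame` with `year` and `age_band` (and `gender`
#'   if modelled).
#' @return Rates per person-year (population cancels: prediction at unit
#'   exposure).
#' @export
predict_rate <- function(model, newdata) {
  stopifnot(inherits(model, "incidence_model"))
  newdata <- as.data.frame(newdata)
  newdata$population <- 1
  as.numeric(predict(model$fit, newdata = newdata, type = "response"))
}

#' Project annual new cases onto a population pyramid
#'
#' Expected count per year = sum over age bands of fitted rate times
#' person-years: `count(y) = sum_b rate(b, y) * population(b, y)`.
#'
#' @param model An [fit_incidence_model()] result.
#' @param pyramid `data.frame` with `year`, `age_band`, `population`
#'   (and `gender` if modelled) covering all requested years and every
#'   modelled age band.
#' @param years Calendar years to project.
#' @return Named numeric vector of projected counts per year.
#' @export
project_new_cases <- function(model, pyramid, years) {
  stopifnot(inherits(model, "incidence_model"))
  pyramid <- as.data.frame(pyramid)
  bands <- levels(model$fit$model$age_band)
  out <- setNames(numeric(length(years)), years)
  for (y in years) {
    cells <- pyramid[pyramid$year == y, , drop = FALSE]
    missing <- setdiff(bands, as.character(cells$age_band))
    if (length(missing))
      stop_her2(sprintf("pyramid is missing cell(s) year %d, age band %s",
                        y, paste(missing, collapse = ", ")))
    cells <- cells[as.character(cells$age_band) %in% bands, , drop = FALSE]
    rates <- predict_rate(model, cells)
    out[as.character(y)] <- sum(rates * cells$population)
  }
  out
}

#' Target cohorts of treated-candidate HER2+ early breast cancer women
#'
#' @param cohort_year Calendar years of diagnosis.
#' @param target_n Target-population size per cohort (HER2+ early,
#'   treated-candidate women).
#' @param total_cases Total incident cases per cohort (optional).
#' @param age_weights Age-at-diagnosis weights shared by the cohorts
#'   (optional `data.frame(age, weight)`), stored as an attribute.
#' @return `data.frame` of class `target_cohorts`.
#' @export
target_cohorts <- function(cohort_year, target_n, total_cases = NA_real_,
                           age_weights = NULL) {
  if (any(!is.na(total_cases) & target_n > total_cases + 1e-9))
    stop_her2("target_n cannot exceed total_cases")
  if (any(target_n < 0)) stop_her2("target_n must be >= 0")
  out <- data.frame(cohort_year = as.integer(cohort_year),
                    total_cases = total_cases, target_n = target_n)
  class(out) <- c("target_cohorts", "data.frame")
  if (!is.null(age_weights)) attr(out, "age_weights") <- age_weights
  out
}

#' Total target population across cohorts
#' @param cohorts A [target_cohorts()] object.
#' @return Sum of `target_n` over cohorts.
#' @export
total_target_population <- function(cohorts) sum(cohorts$target_n)

#' Filter incident cases down to the target population
#'
#' Applies the three multiplicative filters — exclusion of ductal
#' carcinoma in situ, exclusion of de-novo metastatic disease, and HER2+
#' prevalence — to the annual case counts:
#' `target_n = cases * (1 - dcis) * (1 - metastatic) * prevalence(year)`,
#' rounded half-up to an integer per cohort year.  Because the filters
#' are pure multiplications, the order of application is immaterial.
#'
#' @param cases_by_year Named numeric vector (names = cohort years) of
#'   incident case counts, already restricted to the modelled age range.
#' @param dcis_frac Proportion excluded as in-situ ductal carcinoma.
#' @param metastatic_frac Proportion excluded as metastatic at diagnosis.
#' @param her2_prev_by_year HER2+ prevalence: a single proportion, a
#'   named vector per year, or a `data.frame(year, prevalence)`.  Every
#'   cohort year must be covered.
#' @param age_weights Optional age-at-diagnosis weights stored on the
#'   result.
#' @return A [target_cohorts()] object.
#' @export
select_target_population <- function(cases_by_year, dcis_frac,
                                     metastatic_frac, her2_prev_by_year,
                                     age_weights = NULL) {
  check_proportion(dcis_frac, "dcis_frac")
  check_proportion(metastatic_frac, "metastatic_frac")
  years <- as.integer(names(cases_by_year))
  if (any(is.na(years)))
    stop_her2("'cases_by_year' must be named by cohort year")
  prev <- lookup_prevalence(her2_prev_by_year, years)
  check_proportion(prev, "her2_prev_by_year")
  target <- round_half_up(cases_by_year * (1 - dcis_frac) *
                            (1 - metastatic_frac) * prev)
  target_cohorts(years, as.numeric(target),
                 total_cases = as.numeric(cases_by_year),
                 age_weights = age_weights)
}

lookup_prevalence <- function(prev, years) {
  if (is.data.frame(prev)) {
    i <- match(years, prev$year)
    if (any(is.na(i)))
      stop_her2("no HER2+ prevalence for cohort year(s) ",
                paste(years[is.na(i)], collapse = ", "))
    return(prev$prevalence[i])
  }
  if (!is.null(names(prev))) {
    i <- match(as.character(years), names(prev))
    if (any(is.na(i)))
      stop_her2("no HER2+ prevalence for cohort year(s) ",
                paste(years[is.na(i)], collapse = ", "))
    return(as.numeric(prev[i]))
  }
  if (length(prev) == 1L) return(rep(as.numeric(prev), length(years)))
  stop_her2("'her2_prev_by_year' must be scalar, named by year, or a ",
            "data.frame(year, prevalence)")
}
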
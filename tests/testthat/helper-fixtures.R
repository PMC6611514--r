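# Shared fixtures: all synthetic, built in code at test time.

# Annual Weibull survival values on t = 0..k (used as "empirical" KM input)
weibull_annual <- function(params, k) survival_at(params, 0:k)

# km inputs where the empirical segment equals the parametric curve, so
# stitching is exact and analyses are closed-form checkable
exact_km_inputs <- function(followup = 10) {
  kp <- default_km_params()
  lapply(kp, function(p) list(km = weibull_annual(p, followup), params = p))
}

# Small full-model input set: target cohorts straight from the reference
# table, exact Weibull curves, synthetic life table
make_model_inputs <- function(cohort_years = 2006:2017) {
  ref <- reference_estimates()
  i <- match(cohort_years, ref$cohort_years)
  tc <- target_cohorts(cohort_years, ref$target_by_year[i],
                       total_cases = ref$total_bc_cases[i],
                       age_weights = default_age_weights())
  list(cohorts = tc, km = exact_km_inputs(),
       life_table = make_life_table(),
       age_weights = default_age_weights())
}

# Fine-grid (daily) numeric integration of expected person-years for a
# survival function given as a closed form; independent oracle for the
# annual trapezoid engine
fine_grid_ly <- function(sfun, n0, years, step = 1 / 365) {
  tt <- seq(0, years, by = step)
  s <- sfun(tt)
  n0 * sum((s[-1] + s[-length(s)]) / 2 * diff(tt))
}
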
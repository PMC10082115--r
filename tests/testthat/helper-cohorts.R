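# Shared fixture builders: everything is generated in code at test time.

# Working models matching the linear generating process exactly (no
# quadratic or interaction terms): the regime where the closed-form truth
# applies and the estimators reduce to regression coefficients.
linear_specs <- function() {
  fs <- default_formula_specs(interactions = FALSE)
  fs$mediator$poly <- list()
  fs$outcome_conditional$poly <- list()
  fs$outcome_marginal$poly <- list()
  fs
}

linear_config <- function(params, K = 200L, B = 200L, seed = 1L) {
  pipeline_config(params = params, formulas = linear_specs(),
                  estimand = estimand_config(K = K, seed = seed),
                  B = B, seed = seed)
}

# Cohort with quintiles already assigned, plus fitted working models.
fitted_setup <- function(params, specs = linear_specs()) {
  cohort <- generate_cohort(params)
  list(cohort = cohort,
       mediator = fit_mediator_model(cohort, specs$mediator),
       conditional = fit_outcome_model(cohort, specs$outcome_conditional,
                                       conditional_on_mediator = TRUE),
       marginal = fit_outcome_model(cohort, specs$outcome_marginal,
                                    conditional_on_mediator = FALSE))
}

# Degenerate noiseless parameters: mediator 30 min/day, outcome 18 kg/m^2.
degenerate_params <- function(n = 600L, seed = 1L) {
  generating_params(
    n = n,
    mediator = list(intercept = 30, alpha = rep(0, 5), sex = 0, edu = 0,
                    mbmi = 0, sigma = 0),
    outcome = list(intercept = 18, beta = rep(0, 5), gamma = 0, sex = 0,
                   edu = 0, mbmi = 0, sigma = 0),
    seed = seed)
}

expect_within_se <- function(est, truth, se, k = 3) {
  expect_true(all(abs(est - truth) <= k * se),
              label = sprintf("estimate(s) %s within %g SE of %s",
                              paste(round(est, 4), collapse = ","), k,
                              paste(round(truth, 4), collapse = ",")))
}
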
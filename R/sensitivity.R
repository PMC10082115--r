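# Guard: the linear omitted-confounder adjustment needs a conditional
# outcome model with a single mediator coefficient.
check_linear_in_mediator <- function(outcome_model) {
  spec <- outcome_model$spec
  if (!isTRUE(outcome_model$conditional))
    stop("sensitivity adjustment requires the conditional outcome model",
         call. = FALSE)
  if (mediator_degree(spec) > 1L ||
      any(vapply(spec$interactions, function(p) spec$mediator %in% p, TRUE)))
    stop("the omitted-confounder adjustment is only valid for an outcome ",
         "model linear in the mediator with no mediator interaction terms; ",
         "refit with default_formula_specs(interactions = FALSE)",
         call. = FALSE)
}

# gamma(rho): mediator coefficient consistent with residual correlation rho
# between the mediator- and outcome-equation errors.  Standard linear-SEM
# algebra: OLS of Y on (X, M, C) converges to gamma + rho * sigma_Y / sigma_M
# and its residual SD to sigma_Y * sqrt(1 - rho^2), so the true gamma under
# hypothesised rho is recovered from the two fitted residual SDs.
gamma_at_rho <- function(gamma_hat, sigma_cond, sigma_m, rho) {
  gamma_hat - rho * sigma_cond / (sigma_m * sqrt(1 - rho^2))
}

# Refit the non-mediator coefficients with the mediator coefficient pinned
# at gamma_rho (offset regression), returning an outcome model whose
# coefficient vector matches the original design columns.
constrained_outcome_model <- function(cohort, outcome_model, gamma_rho) {
  spec <- outcome_model$spec
  spec_nom <- spec
  spec_nom$mediator <- NULL
  spec_nom$vars <- setdiff(spec$vars, spec$mediator)
  rows <- which(complete.cases(
    cohort[, c(spec$response, spec$vars), drop = FALSE]))
  dat <- cohort[rows, , drop = FALSE]
  levels_info <- record_levels(spec, dat)
  Z <- build_design(spec_nom, dat, levels_info)
  y <- dat[[spec$response]] - gamma_rho * dat[[spec$mediator]]
  fit <- lm.fit(Z, y)
  adj <- outcome_model
  coefs <- setNames(numeric(length(outcome_model$coef)),
                    names(outcome_model$coef))
  coefs[names(fit$coefficients)] <- fit$coefficients
  coefs[spec$mediator] <- gamma_rho
  adj$coef <- coefs
  adj$levels <- levels_info
  df <- nrow(Z) - ncol(Z)
  adj$sigma <- if (df > 0) sqrt(sum(fit$residuals^2) / df) else 0
  adj
}

#' Disparity difference under hypothesised unmeasured confounding
#'
#' Adjusts the mediator coefficient of the conditional outcome model for an
#' unmeasured mediator-outcome confounder hypothesised to induce residual
#' correlation `rho` between the mediator- and outcome-model errors, refits
#' the remaining coefficients under that constraint, and recomputes
#' `difference_j = Adj-TA_j - IDM-DE_j` for the selected contrast.  The
#' IDM-DE is recomputed with the deterministic quadrature integrator so the
#' adjusted difference carries no Monte-Carlo noise.  At `rho = 0` the
#' unadjusted difference is reproduced exactly.
#'
#' @param cohort A cohort data frame.
#' @param mediator_model A fitted [fit_mediator_model()].
#' @param outcome_model The conditional outcome model; must be linear in the
#'   mediator with no mediator interactions (the adjustment formula's
#'   domain).
#' @param outcome_model_marginal The marginal outcome model (the Adj-TA does
#'   not depend on `rho`).
#' @param rho Hypothesised residual correlation, `|rho| < 1`.
#' @param config An [estimand_config()]; draws are not used (quadrature).
#' @param contrast Exposure level to contrast against the reference
#'   (default 5, top vs bottom quintile).
#' @return The adjusted difference (kg/m^2, numeric scalar).
#' @export
adjusted_difference_at_rho <- function(cohort, mediator_model, outcome_model,
                                       outcome_model_marginal, rho,
                                       config = estimand_config(),
                                       contrast = 5L) {
  check_scalar(rho, "rho")
  if (abs(rho) >= 1) stop_field("rho", "must satisfy |rho| < 1")
  check_linear_in_mediator(outcome_model)
  cfg <- config
  cfg$truncate_draws <- FALSE
  gamma_hat <- outcome_model$coef[[outcome_model$spec$mediator]]
  g_rho <- gamma_at_rho(gamma_hat, outcome_model$sigma,
                        mediator_model$sigma, rho)
  adj_model <- if (rho == 0) outcome_model else
    constrained_outcome_model(cohort, outcome_model, g_rho)
  idm <- numeric_oracle(cohort, mediator_model, adj_model, cfg)
  adj_ta <- estimate_adj_ta(cohort, outcome_model_marginal, cfg)
  unname(adj_ta[as.character(contrast)] - idm[as.character(contrast)])
}

#' Minimal confounder-induced correlation nullifying the mediator's impact
#'
#' Scans the adjusted disparity difference over a grid of hypothesised
#' residual correlations and locates, by bisection on the deterministic
#' quadrature integrator, the correlation `rho*` at which the difference
#' crosses zero: the minimal correlation an omitted mediator-outcome
#' confounder would need to induce for the hypothetical mediator
#' intervention to have no impact.  `rho*` inherits the sign of the observed
#' residual mediator-outcome association.  An optional percentile bootstrap
#' (models refit and `rho*` re-located on each resample) yields a 95%
#' interval.
#'
#' @param cohort A cohort data frame.
#' @param config A [pipeline_config()]; its conditional outcome formula must
#'   be linear in the mediator (see [default_formula_specs()] with
#'   `interactions = FALSE`).
#' @param contrast Exposure contrast analysed (default 5).
#' @param grid Grid of rho values for the reported sensitivity curve.
#' @param interval Search interval for the root.
#' @param B Bootstrap replicates for the `rho*` interval (0 = none).
#' @param seed Seed for the bootstrap.
#' @return An object of class `sensitivity_result`: the (rho, difference)
#'   curve, `rho_star` (or `NA` with `no_crossing = TRUE` if the difference
#'   never changes sign on the interval), and the bootstrap interval when
#'   requested.
#' @export
find_null_rho <- function(cohort, config, contrast = 5L,
                          grid = seq(-0.5, 0.5, length.out = 41),
                          interval = c(-0.95, 0.95), B = 0L,
                          seed = config$seed) {
  stopifnot(inherits(config, "pipeline_config"))
  rho_star_once <- function(dat, cfg, draw_seed, with_curve = FALSE) {
    keep <- !is.na(dat$pgs)
    dat <- dat[keep, , drop = FALSE]
    dat$exposure_quintile <- assign_quintiles(dat$pgs)
    med <- fit_mediator_model(dat, cfg$formulas$mediator)
    out_c <- fit_outcome_model(dat, cfg$formulas$outcome_conditional, TRUE)
    out_m <- fit_outcome_model(dat, cfg$formulas$outcome_marginal, FALSE)
    f <- function(rho) adjusted_difference_at_rho(dat, med, out_c, out_m,
                                                  rho, cfg$estimand,
                                                  contrast)
    f_lo <- f(interval[1]); f_hi <- f(interval[2])
    root <- if (sign(f_lo) == sign(f_hi)) NA_real_ else
      uniroot(f, interval, f.lower = f_lo, f.upper = f_hi,
              tol = 1e-10)$root
    if (!with_curve) return(c(rho_star = root))
    list(rho_star = root,
         curve = data.frame(rho = grid,
                            difference = vapply(grid, f, numeric(1))),
         crossed = !is.na(root))
  }

  main <- rho_star_once(cohort, config, derive_seed(seed, 0),
                        with_curve = TRUE)

  ci <- NULL
  if (B >= 2) {
    eng <- boot_engine(cohort, config, B, seed,
                       function(dat, cfg, ds) rho_star_once(dat, cfg, ds))
    ci <- unname(quantile(eng$reps[, "rho_star"], c(0.025, 0.975),
                          na.rm = TRUE))
  }
  structure(list(curve = main$curve, rho_star = main$rho_star,
                 ci = ci, contrast = contrast,
                 no_crossing = is.na(main$rho_star), B = B),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, digits = 4, ...) {
  cat(sprintf("Unmeasured mediator-outcome confounding sensitivity %s\n",
              sprintf("(contrast %s vs reference)", x$contrast)))
  if (x$no_crossing) {
    cat("  no sign change on the search interval: the adjusted difference ",
        "never crosses zero\n")
  } else {
    cat(sprintf("  rho* = %.*f", digits, x$rho_star))
    if (!is.null(x$ci))
      cat(sprintf("  (95%% bootstrap CI %.*f, %.*f; B = %d)",
                  digits, x$ci[1], digits, x$ci[2], x$B))
    cat("\n")
  }
  invisible(x)
}
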
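# Least-squares fit of a formula_spec on the complete rows of a cohort.
# `drop_constant` names design columns (the degenerate mediator case) whose
# zero-variance incarnation is excluded with coefficient 0 rather than
# triggering the rank-deficiency error: a mediator with no variation carries
# no estimable effect.
fit_parametric <- function(spec, data, min_ratio = 10,
                           drop_constant = character(0)) {
  keep <- complete.cases(data[, c(spec$response, spec$vars), drop = FALSE])
  rows <- data[keep, , drop = FALSE]
  levels_info <- record_levels(spec, rows)
  Z <- build_design(spec, rows, levels_info)
  y <- as.numeric(rows[[spec$response]])

  zeroed <- character(0)
  for (dc in intersect(drop_constant, colnames(Z))) {
    if (var(Z[, dc]) == 0) {
      zeroed <- c(zeroed, dc)
      warning(sprintf(paste0("'%s' has no variation in the fitting data; ",
                             "its coefficient is set to 0"), dc),
              call. = FALSE)
    }
  }
  Zfit <- if (length(zeroed)) Z[, setdiff(colnames(Z), zeroed),
                               drop = FALSE] else Z
  p <- ncol(Zfit)
  if (nrow(Zfit) < min_ratio * p)
    stop(sprintf(paste0("insufficient complete rows to fit '%s' model: %d ",
                        "rows for %d coefficients (need >= %d)"),
                 spec$response, nrow(Zfit), p, ceiling(min_ratio * p)),
         call. = FALSE)
  fit <- lm.fit(Zfit, y)
  if (fit$rank < p) {
    aliased <- colnames(Zfit)[fit$qr$pivot[(fit$rank + 1):p]]
    stop("rank-deficient design; collinear terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  res <- fit$residuals
  rss <- sum(res^2)
  df <- nrow(Zfit) - p
  sigma <- if (df > 0) sqrt(rss / df) else 0
  tss <- sum((y - mean(y))^2)
  piv <- fit$qr$pivot
  Vp <- chol2inv(qr.R(fit$qr))
  V <- matrix(0, p, p)
  V[piv, piv] <- Vp
  se_fit <- sqrt(pmax(diag(V), 0)) * sigma

  coef <- setNames(numeric(ncol(Z)), colnames(Z))
  se <- coef
  coef[names(fit$coefficients)] <- fit$coefficients
  se[colnames(Zfit)] <- se_fit
  structure(
    list(spec = spec, coef = coef, se = se,
         sigma = sigma, n = nrow(Zfit), df_resid = df,
         r2 = if (tss > 0) 1 - rss / tss else NA_real_,
         levels = levels_info, rows_used = which(keep)),
    class = "pgd_fit")
}

#' Fit the parametric mediator model f(M | X, C)
#'
#' Ordinary least squares on rows with complete data for all model variables,
#' with a homoscedastic Gaussian residual model whose SD feeds the
#' Monte-Carlo mediator draws.
#'
#' @param cohort A cohort data frame.
#' @param spec A [formula_spec()] whose response is the mediator (defaults to
#'   the package default mediator specification).
#' @return An object of class `c("mediator_model", "pgd_fit")` carrying the
#'   coefficients (including the per-quintile shifts), residual SD
#'   `sigma`, coefficient standard errors, `n` used and R^2.
#' @export
fit_mediator_model <- function(cohort, spec = default_formula_specs()$mediator) {
  stopifnot(inherits(spec, "formula_spec"))
  if (!is.null(spec$mediator))
    stop("the mediator model's own response may not also be a predictor",
         call. = FALSE)
  fit <- fit_parametric(spec, cohort)
  class(fit) <- c("mediator_model", class(fit))
  fit
}

#' Fit a parametric outcome model
#'
#' Fits either the conditional outcome model E(Y | X, M, C) (used inside the
#' IDM-DE standardisation) or the marginal outcome model E(Y | X, C) (used
#' for the Adj-TA).
#'
#' @param cohort A cohort data frame.
#' @param spec A [formula_spec()] for the outcome.
#' @param conditional_on_mediator Logical; if `TRUE` the spec must include
#'   the mediator, if `FALSE` it must not.
#' @return An object of class `c("outcome_model", "pgd_fit")` with a
#'   `conditional` flag.
#' @export
fit_outcome_model <- function(cohort, spec, conditional_on_mediator) {
  stopifnot(inherits(spec, "formula_spec"),
            is.logical(conditional_on_mediator))
  if (conditional_on_mediator && is.null(spec$mediator))
    stop("conditional outcome model must include the mediator", call. = FALSE)
  if (!conditional_on_mediator && !is.null(spec$mediator))
    stop("marginal outcome model must not contain a mediator term",
         call. = FALSE)
  fit <- fit_parametric(spec, cohort,
                        drop_constant = if (conditional_on_mediator)
                          spec$mediator else character(0))
  fit$conditional <- conditional_on_mediator
  class(fit) <- c("outcome_model", class(fit))
  fit
}

#' @export
print.pgd_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Parametric %s model (n = %d, sigma = %.4g, R^2 = %.3f)\n",
              x$spec$response, x$n, x$sigma, x$r2))
  print(round(rbind(estimate = x$coef, se = x$se), digits))
  invisible(x)
}

#' Predicted mean from a fitted working model
#'
#' @param model A fitted model from [fit_mediator_model()] or
#'   [fit_outcome_model()].
#' @param newdata Data frame of covariate rows.
#' @param exposure_level Optional: force the exposure to this level for all
#'   rows (must be one of the levels seen at fit time).
#' @param mediator_value Optional scalar or vector forcing the mediator.
#' @return Numeric vector of predicted means.
#' @export
predict_mean <- function(model, newdata, exposure_level = NULL,
                         mediator_value = NULL) {
  stopifnot(inherits(model, "pgd_fit"))
  if (!is.null(exposure_level)) {
    if (!exposure_level %in% model$levels$exposure)
      stop(sprintf("exposure level '%s' was not present at fit time",
                   exposure_level), call. = FALSE)
  }
  Z <- build_design(model$spec, newdata, model$levels,
                    exposure_override = exposure_level,
                    mediator_override = mediator_value)
  drop(Z %*% model$coef)
}

#' Draw mediator values from the fitted conditional distribution
#'
#' For each covariate row, draws `n_draws` independent values from
#' `Normal(mu(X = exposure_level, C = row), sigma_M)`, left-truncated at zero
#' (activity time cannot be negative).  Draws use a dedicated deterministic
#' stream given `seed` and do not disturb R's global random-number state.
#'
#' @param model A fitted [fit_mediator_model()].
#' @param covariate_rows Data frame of confounder rows.
#' @param exposure_level Exposure level at which to set X (typically the
#'   reference, for the hypothetical mediator-shift intervention).
#' @param n_draws Number of draws per row.
#' @param seed Integer seed.
#' @param truncate Left-truncate at 0 (default `TRUE`).  Disable only for
#'   oracle-equivalence checks against untruncated quadrature.
#' @return Numeric matrix, `nrow(covariate_rows)` by `n_draws`.
#' @export
draw_mediator <- function(model, covariate_rows, exposure_level, n_draws,
                          seed, truncate = TRUE) {
  stopifnot(inherits(model, "mediator_model"))
  check_scalar(n_draws, "n_draws", positive = TRUE, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  mu <- predict_mean(model, covariate_rows, exposure_level = exposure_level)
  cpp_truncnorm_draws(mu, model$sigma, as.integer(n_draws), as.double(seed),
                      truncate)
}

# Per-row draw moments E_hat[M^d] over the identical stream as draw_mediator.
mediator_draw_moments <- function(model, covariate_rows, exposure_level,
                                  n_draws, seed, truncate, degree) {
  mu <- predict_mean(model, covariate_rows, exposure_level = exposure_level)
  cpp_truncnorm_moments(mu, model$sigma, as.integer(n_draws),
                        as.double(seed), truncate, as.integer(degree))
}
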
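#' Specification of the single stochastic chained-equations imputation
#'
#' Missing values are filled by fully conditional specification: after an
#' initial fill drawn from each variable's observed marginal, the incomplete
#' variables are cycled through `burn_in` times in increasing order of
#' missingness fraction (ties alphabetical); on each visit the variable's
#' conditional model is refit to the rows where it is observed (with current
#' imputations in the predictors) and the missing cells are replaced by
#' stochastic draws, not conditional means.  Each conditional model includes
#' all other analysis variables; continuous targets additionally get a
#' maternal-BMI quadratic term and a mediator-by-sex interaction, mirroring
#' the analysis models.  Families: continuous variables use linear
#' regression with a normal residual draw (respecting the variable's
#' support), binary variables logistic regression with a Bernoulli draw,
#' ordinal variables a proportional-odds model with a category draw.
#'
#' A single imputation carries no between-imputation uncertainty; interval
#' estimates on imputed data must come from [bootstrap_pipeline()] with the
#' imputation redone inside each replicate.
#'
#' @param variables Variables eligible for imputation (those actually
#'   incomplete are imputed).
#' @param burn_in Number of full cycles (default 10, minimum 1).
#' @param seed Integer seed.
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(variables = c("mediator", "outcome",
                                          "maternal_bmi"),
                            burn_in = 10L, seed = 1L) {
  check_scalar(burn_in, "burn_in", positive = TRUE, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  stopifnot(is.character(variables), length(variables) >= 1)
  structure(list(variables = variables, burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

# Conditional-model spec for imputing `target` from the other analysis
# variables present in the cohort.
impute_model_spec <- function(target, cohort) {
  analysis_vars <- intersect(
    c("exposure_quintile", "mediator", "outcome", "sex",
      "maternal_education", "maternal_bmi"), names(cohort))
  preds <- setdiff(analysis_vars, target)
  continuous <- target %in% c("mediator", "outcome", "maternal_bmi", "pgs")
  poly <- if (continuous && "maternal_bmi" %in% preds)
    list(maternal_bmi = 2) else list()
  inter <- if (continuous && all(c("mediator", "sex") %in% preds))
    list(c("mediator", "sex")) else list()
  formula_spec(target,
               exposure = if ("exposure_quintile" %in% preds)
                 "exposure_quintile" else NULL,
               confounders = setdiff(preds, c("exposure_quintile",
                                              "mediator")),
               mediator = if ("mediator" %in% preds) "mediator" else NULL,
               factors = "maternal_education", poly = poly,
               interactions = inter)
}

impute_family <- function(target, cohort) {
  x <- cohort[[target]]
  obs <- x[!is.na(x)]
  k <- length(unique(obs))
  if (target == "sex" || k == 2) "binary"
  else if (target %in% c("maternal_education", "exposure_quintile") ||
             (k <= 8 && all(obs == round(obs)))) "ordinal"
  else "continuous"
}

# One stochastic update of `target` given current completed data.
impute_draw <- function(target, cohort, miss_idx) {
  spec <- impute_model_spec(target, cohort)
  levels_info <- record_levels(spec, cohort)
  Z <- build_design(spec, cohort, levels_info)
  obs <- !seq_len(nrow(cohort)) %in% miss_idx
  family <- impute_family(target, cohort)
  y <- cohort[[target]]

  if (family == "continuous") {
    fit <- lm.fit(Z[obs, , drop = FALSE], y[obs])
    keep <- !is.na(fit$coefficients)
    mu <- drop(Z[miss_idx, keep, drop = FALSE] %*% fit$coefficients[keep])
    df <- sum(obs) - sum(keep)
    s <- if (df > 0) sqrt(sum(fit$residuals^2) / df) else 0
    lower <- if (target %in% c("mediator", "outcome", "maternal_bmi"))
      0 else -Inf
    if (is.finite(lower))
      truncate_resample(mu, s, lower = lower, open = target == "outcome")
    else mu + s * rnorm(length(mu))
  } else if (family == "binary") {
    lv <- sort(unique(y[obs]))
    fit <- suppressWarnings(
      glm.fit(Z[obs, , drop = FALSE], as.numeric(y[obs] == lv[2]),
              family = binomial()))
    keep <- !is.na(fit$coefficients)
    p <- plogis(drop(Z[miss_idx, keep, drop = FALSE] %*%
                       fit$coefficients[keep]))
    lv[1 + rbinom(length(p), 1, p)]
  } else {
    dat <- as.data.frame(Z[, -1, drop = FALSE])
    names(dat) <- make.names(colnames(Z)[-1])
    dat$.y <- factor(y, levels = sort(unique(y[obs])), ordered = TRUE)
    fit <- suppressWarnings(
      MASS::polr(.y ~ ., data = dat[obs, , drop = FALSE]))
    pr <- predict(fit, newdata = dat[miss_idx, , drop = FALSE],
                  type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
    lv <- as.numeric(colnames(pr))
    vapply(seq_len(nrow(pr)), function(i)
      sample(lv, 1L, prob = pr[i, ]), numeric(1))
  }
}

#' Impute missing values by single stochastic chained equations
#'
#' @param cohort A cohort data frame with missing cells.
#' @param spec An [imputation_spec()].
#' @return The completed cohort (no missing cells among the spec's
#'   variables); observed cells are never altered.  Deterministic given
#'   `spec$seed`.  The originally missing cells are recorded in attribute
#'   `"imputed_cells"`.
#' @export
impute_chained <- function(cohort, spec = imputation_spec()) {
  stopifnot(is.data.frame(cohort), inherits(spec, "imputation_spec"))
  vars <- intersect(spec$variables, names(cohort))
  miss <- lapply(setNames(vars, vars),
                 function(v) which(is.na(cohort[[v]])))
  miss <- miss[lengths(miss) > 0]
  if (!length(miss)) return(cohort)

  for (v in names(miss)) {
    if (all(is.na(cohort[[v]])))
      stop(sprintf("variable '%s' has no observed values; cannot impute", v),
           call. = FALSE)
  }
  other_na <- setdiff(names(cohort)[vapply(cohort, anyNA, TRUE)],
                      c(names(miss), spec$variables))
  if (length(other_na))
    stop("variables outside the imputation spec contain missing values: ",
         paste(other_na, collapse = ", "), call. = FALSE)
  fully_obs <- setdiff(names(cohort), names(miss))
  if (!length(fully_obs))
    stop("chained equations need at least one fully observed variable",
         call. = FALSE)

  frac <- vapply(names(miss), function(v) length(miss[[v]]) / nrow(cohort),
                 numeric(1))
  visit <- names(miss)[order(frac, names(miss))]

  with_seed(spec$seed, {
    completed <- cohort
    for (v in visit) {
      idx <- miss[[v]]
      obs_vals <- completed[[v]][-idx]
      completed[[v]][idx] <- sample(obs_vals, length(idx), replace = TRUE)
    }
    for (cycle in seq_len(spec$burn_in)) {
      for (v in visit)
        completed[[v]][miss[[v]]] <- impute_draw(v, completed, miss[[v]])
    }
    for (v in visit) {  # categorical draws must not retype integer columns
      if (is.integer(cohort[[v]]))
        completed[[v]] <- as.integer(round(completed[[v]]))
    }
    structure(completed, imputed_cells = miss)
  })
}
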
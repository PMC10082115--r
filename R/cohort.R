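#' Assign equal-sized quantile groups to a continuous score
#'
#' Categorises a polygenic score into cohort-specific quintiles (or another
#' number of equal-sized groups).  Assignment is rank-based, so any strictly
#' monotone transform of the score yields identical labels, and with distinct
#' values the group sizes differ by at most one.  Tied values all receive the
#' lower group (the boundary value goes to the lower quintile).
#'
#' @param x Numeric vector of scores (no missing values; at least `n_groups`
#'   values, not all identical).
#' @param n_groups Number of groups (default 5, quintiles).
#' @return Integer labels in `1..n_groups`, 1 = lowest score.
#' @export
#' @examples
#' assign_quintiles(1:10)  # 1 1 2 2 3 3 4 4 5 5
assign_quintiles <- function(x, n_groups = 5L) {
  if (anyNA(x)) stop("scores contain missing values", call. = FALSE)
  if (length(x) < n_groups)
    stop(sprintf("need at least %d values to form %d groups",
                 n_groups, n_groups), call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("all scores are identical; quantile groups are undefined",
         call. = FALSE)
  r <- rank(x, ties.method = "min")
  as.integer(floor((r - 1) * n_groups / length(x)) + 1L)
}

#' Generate a fully observed synthetic cohort
#'
#' Simulates a cohort with the structure the disparity analysis assumes:
#' confounders first, then the polygenic score, quintile assignment by
#' empirical quantiles, the mediator from its structural equation
#' (left-truncated at zero by resampling the residual), and finally the
#' outcome (truncated to be positive, a negligible-probability event under
#' sensible parameters).  Fully deterministic given `params$seed`.
#'
#' @param params A [generating_params()] object.
#' @return A `cohort_table` data frame with columns `id`, `pgs`,
#'   `exposure_quintile`, `mediator` (min/day), `outcome` (kg/m^2), `sex`
#'   (0/1), `maternal_education` (integer level), `maternal_bmi` (kg/m^2).
#'   Missing cells (none at this stage) are encoded as `NA`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generating_params"))
  n <- params$n
  cf <- params$confounders
  med <- params$mediator
  out <- params$outcome

  with_seed(params$seed, {
    sex <- rbinom(n, 1, cf$sex_p)
    edu <- sample.int(length(cf$edu_probs), n, replace = TRUE,
                      prob = cf$edu_probs)
    mbmi <- rnorm(n, cf$mbmi_mean, cf$mbmi_sd)
    u <- rnorm(n)

    mbmi_c <- mbmi - cf$mbmi_mean
    edu_c <- edu - 2
    pgs <- rnorm(n) + params$pgs$sex * (sex - cf$sex_p) +
      params$pgs$edu * edu_c + params$pgs$mbmi * mbmi_c
    quintile <- assign_quintiles(pgs)

    mu_m <- med$intercept + med$alpha[quintile] + med$sex * sex +
      med$edu * edu_c + med$mbmi * mbmi_c + med$sex_mbmi * sex * mbmi_c +
      params$latent[["m"]] * u
    mediator <- truncate_resample(mu_m, med$sigma, lower = 0)

    mu_y <- out$intercept + out$beta[quintile] + out$gamma * mediator +
      out$sex * sex + out$edu * edu_c + out$mbmi * mbmi_c +
      out$mbmi2 * mbmi_c^2 + out$med_sex * mediator * sex +
      out$med_mbmi * mediator * mbmi_c + params$latent[["y"]] * u
    outcome <- truncate_resample(mu_y, out$sigma, lower = 0, open = TRUE)

    structure(
      data.frame(id = seq_len(n), pgs = pgs, exposure_quintile = quintile,
                 mediator = mediator, outcome = outcome, sex = sex,
                 maternal_education = edu, maternal_bmi = mbmi),
      class = c("cohort_table", "data.frame"))
  })
}

# mu + sigma * e with e resampled until mu + sigma * e is admissible.
truncate_resample <- function(mu, sigma, lower, open = FALSE, max_iter = 200) {
  if (sigma == 0) {
    x <- mu
    bad <- if (open) x <= lower else x < lower
    if (any(bad))
      stop("degenerate (zero-noise) values fall outside the variable's ",
           "support", call. = FALSE)
    return(x)
  }
  x <- mu + sigma * rnorm(length(mu))
  for (i in seq_len(max_iter)) {
    bad <- if (open) x <= lower else x < lower
    if (!any(bad)) return(x)
    x[bad] <- mu[bad] + sigma * rnorm(sum(bad))
  }
  # essentially unreachable under sane parameters: exact inverse-CDF fallback
  bad <- if (open) x <= lower else x < lower
  p_lo <- pnorm(lower, mu[bad], sigma)
  x[bad] <- qnorm(p_lo + (1 - p_lo) * runif(sum(bad)), mu[bad], sigma)
  x
}

#' Specification of a missing-at-random missingness mechanism
#'
#' Each target variable is made missing with probability
#' `plogis(b0 + sum(coefs * centred predictors))`, where the intercept `b0`
#' is calibrated so the average missingness probability equals `rate`.
#' Predictors must be fully observed variables, so the mechanism is missing
#' at random given the observed data; a target may not predict its own
#' missingness (that would be self-masking, MNAR-like).
#'
#' @param targets Named list; each element describes one target variable and
#'   is a list with `rate` (target missing fraction in `[0, 1)`) and
#'   optionally `coefs` (named numeric of logistic loadings on fully observed
#'   predictor variables, per unit of the centred predictor).
#' @param seed Integer seed.
#' @return An object of class `missingness_spec`.
#' @export
#' @examples
#' missingness_spec(list(mediator = list(rate = 0.3,
#'                                       coefs = c(maternal_bmi = 0.1))))
missingness_spec <- function(targets, seed = 1L) {
  stopifnot(is.list(targets), length(names(targets)) == length(targets))
  check_scalar(seed, "seed", integer = TRUE)
  for (v in names(targets)) {
    t <- targets[[v]]
    if (is.null(t$rate) || t$rate < 0 || t$rate >= 1)
      stop_field(paste0("targets$", v, "$rate"), "must lie in [0, 1)")
    coefs <- t$coefs %||% numeric(0)
    if (length(coefs) && is.null(names(coefs)))
      stop_field(paste0("targets$", v, "$coefs"), "must be named")
    if (v %in% names(coefs))
      stop(sprintf(paste0("target variable '%s' may not predict its own ",
                          "missingness (self-masking would violate MAR)"),
                   v), call. = FALSE)
  }
  structure(list(targets = targets, seed = as.integer(seed)),
            class = "missingness_spec")
}

#' Apply MAR missingness to a cohort
#'
#' @param cohort A `cohort_table` data frame.
#' @param spec A [missingness_spec()].
#' @return The cohort with target cells set to `NA`; non-target cells are
#'   untouched.  Deterministic given `spec$seed`.
#' @export
induce_missingness <- function(cohort, spec) {
  stopifnot(is.data.frame(cohort), inherits(spec, "missingness_spec"))
  with_seed(spec$seed, {
    for (v in names(spec$targets)) {
      t <- spec$targets[[v]]
      if (!v %in% names(cohort))
        stop(sprintf("target variable '%s' not found in cohort", v),
             call. = FALSE)
      if (t$rate == 0) next
      coefs <- t$coefs %||% numeric(0)
      lp <- rep(0, nrow(cohort))
      for (p in names(coefs)) {
        if (!p %in% names(cohort))
          stop(sprintf("missingness predictor '%s' not found in cohort", p),
               call. = FALSE)
        x <- cohort[[p]]
        if (anyNA(x))
          stop(sprintf(paste0("missingness predictor '%s' is not fully ",
                              "observed; the mechanism would not be MAR"),
                       p), call. = FALSE)
        lp <- lp + coefs[[p]] * (x - mean(x))
      }
      b0 <- if (all(lp == 0)) stats::qlogis(t$rate) else
        uniroot(function(b) mean(plogis(b + lp)) - t$rate,
                interval = c(-30, 30), tol = 1e-10)$root
      miss <- runif(nrow(cohort)) < plogis(b0 + lp)
      cohort[[v]][miss] <- NA
    }
    cohort
  })
}

#' Write / read a cohort CSV
#'
#' Fixed column schema `id, pgs, exposure_quintile, mediator, outcome, sex,
#' maternal_education, maternal_bmi`; missing cells are written as empty
#' fields.  A JSON sidecar (`<path>.meta.json`) records the generating seed
#' when known.
#'
#' @param cohort A `cohort_table` data frame.
#' @param path Output CSV path.
#' @param seed Optional seed to record in the sidecar metadata.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  cols <- c("id", "pgs", "exposure_quintile", "mediator", "outcome", "sex",
            "maternal_education", "maternal_bmi")
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  write.csv(cohort[cols], path, row.names = FALSE, na = "")
  meta <- list(schema = cols, n = nrow(cohort))
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, na.strings = "")
  structure(x, class = c("cohort_table", "data.frame"))
}

#' Serialise generating parameters to / from YAML
#'
#' @param params A [generating_params()] object.
#' @param path YAML file path.
#' @return For `write_params`, `path` invisibly; for `read_params`, a
#'   validated [generating_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "generating_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  generating_params(n = x$n, confounders = x$confounders, pgs = x$pgs,
                    mediator = x$mediator, outcome = x$outcome,
                    latent = unlist(x$latent), seed = x$seed)
}

#' Serialise a missingness specification to / from YAML
#'
#' @param spec A [missingness_spec()].
#' @param path YAML file path.
#' @return For `write_missingness`, `path` invisibly; for
#'   `read_missingness`, a validated [missingness_spec()].
#' @export
write_missingness <- function(spec, path) {
  stopifnot(inherits(spec, "missingness_spec"))
  out <- unclass(spec)
  # named vectors of length one lose their names as YAML scalars: store the
  # logistic loadings as an explicit map
  out$targets <- lapply(out$targets, function(t) {
    if (!is.null(t$coefs)) t$coefs <- as.list(t$coefs)
    t
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_missingness
#' @export
read_missingness <- function(path) {
  x <- yaml::read_yaml(path)
  targets <- lapply(x$targets, function(t) {
    if (!is.null(t$coefs)) t$coefs <- unlist(t$coefs)
    t
  })
  missingness_spec(targets, seed = x$seed)
}
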
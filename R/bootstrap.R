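#' Full pipeline configuration
#'
#' Bundles everything one analysis needs: a cohort source (an input CSV path
#' or simulation parameters, exactly one), the three working-model
#' specifications, the estimand configuration, an optional missingness
#' mechanism (applied after simulation) and imputation specification, the
#' bootstrap replicate count, the sensitivity grid, and a master seed from
#' which every downstream seed is derived.
#'
#' @param input Path to a cohort CSV (see [read_cohort()]), or `NULL`.
#' @param params A [generating_params()] object, or `NULL`.
#' @param formulas Named list as returned by [default_formula_specs()].
#' @param estimand An [estimand_config()].
#' @param missingness Optional [missingness_spec()] applied to a simulated
#'   cohort.
#' @param imputation Optional [imputation_spec()]; when present the pipeline
#'   additionally runs the imputed-data sensitivity analysis with the
#'   imputation redone inside each bootstrap replicate.
#' @param B Bootstrap replicate count.
#' @param sensitivity List with `contrast` (default 5) and `grid` (rho values
#'   for the sensitivity curve), or `NULL` to skip the confounding
#'   sensitivity stage.
#' @param output_dir Output directory for [run_analysis()] (`NULL` = return
#'   results only).
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, params = NULL,
                            formulas = default_formula_specs(),
                            estimand = estimand_config(),
                            missingness = NULL, imputation = NULL,
                            B = 1000L,
                            sensitivity = list(contrast = 5L,
                                               grid = seq(-0.5, 0.5,
                                                          length.out = 41)),
                            output_dir = NULL, seed = 1L) {
  if (is.null(input) == is.null(params))
    stop("exactly one of 'input' (cohort CSV path) and 'params' ",
         "(simulation parameters) must be supplied", call. = FALSE)
  if (!is.null(params)) stopifnot(inherits(params, "generating_params"))
  stopifnot(inherits(estimand, "estimand_config"))
  check_scalar(B, "B", positive = TRUE, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(input = input, params = params, formulas = formulas,
                 estimand = estimand, missingness = missingness,
                 imputation = imputation, B = as.integer(B),
                 sensitivity = sensitivity, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Re-derive cohort-specific quintiles, fit the three working models and
# compute the estimands.  `draw_seed` seeds the Monte-Carlo mediator draws.
fit_and_estimate <- function(cohort, config, draw_seed) {
  keep <- !is.na(cohort$pgs)
  cohort <- cohort[keep, , drop = FALSE]
  cohort$exposure_quintile <- assign_quintiles(cohort$pgs)
  med <- fit_mediator_model(cohort, config$formulas$mediator)
  out_c <- fit_outcome_model(cohort, config$formulas$outcome_conditional,
                             conditional_on_mediator = TRUE)
  out_m <- fit_outcome_model(cohort, config$formulas$outcome_marginal,
                             conditional_on_mediator = FALSE)
  cfg <- config$estimand
  cfg$seed <- as.integer(draw_seed)
  estimate_disparity(cohort, med, out_c, out_m, cfg)
}

flatten_disparity <- function(est) {
  setNames(c(est$adj_ta, est$idm_de, est$difference),
           c(paste0("adj_ta_", est$contrast),
             paste0("idm_de_", est$contrast),
             paste0("difference_", est$contrast)))
}

# Shared resampling engine: resamples rows with replacement, redoes the
# imputation (replicate-specific substream) when enabled, and evaluates
# `statistic(cohort, config, draw_seed)` -> named numeric.
boot_engine <- function(cohort, config, B, seed, statistic) {
  n <- nrow(cohort)
  point_cohort <- cohort
  if (!is.null(config$imputation)) {
    point_cohort <- impute_chained(cohort, config$imputation)
  }
  point <- statistic(point_cohort, config, derive_seed(seed, 0))

  reps <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, names(point)))
  failed <- 0L
  for (r in seq_len(B)) {
    rs <- derive_seed(seed, r)
    idx <- with_seed(rs, sample.int(n, n, replace = TRUE))
    boot <- cohort[idx, , drop = FALSE]
    val <- tryCatch({
      if (!is.null(config$imputation)) {
        ispec <- config$imputation
        ispec$seed <- derive_seed(rs, 1)
        boot <- impute_chained(boot, ispec)
      }
      statistic(boot, config, derive_seed(rs, 2))
    }, error = function(e) NULL)
    if (is.null(val) || !identical(names(val), names(point))) {
      failed <- failed + 1L
    } else {
      reps[r, ] <- val
    }
  }
  if (failed > 0.1 * B)
    stop(sprintf("%d of %d bootstrap replicates failed; results unreliable",
                 failed, B), call. = FALSE)
  list(point = point, reps = reps[stats::complete.cases(reps), ,
                                  drop = FALSE], failed = failed)
}

#' Percentile bootstrap for the full disparity pipeline
#'
#' Resamples participants with replacement (n out of n) `B` times and reruns
#' the complete pipeline on each replicate: imputation (if enabled, with a
#' replicate-specific random stream), quintile re-assignment on the resample
#' (the exposure categories are cohort-specific), model fits, and both
#' estimands.  Confidence bounds are the 2.5th and 97.5th percentiles of the
#' replicate distribution.  Replicates that fail to fit (for example an
#' exposure level emptying out after resampling) are recorded and skipped;
#' more than 10% failures aborts.
#'
#' @param cohort A cohort data frame.
#' @param config A [pipeline_config()].
#' @param B Number of bootstrap replicates (default `config$B`).
#' @param seed Integer seed; replicate `r` uses a substream derived from it.
#' @return A `bootstrap_result` data frame with columns `estimand`,
#'   `contrast`, `estimate` (from the original sample), `lower`, `upper`,
#'   and attributes `B`, `failed`, `seed`, `warnings`.
#' @export
bootstrap_pipeline <- function(cohort, config, B = config$B,
                               seed = config$seed) {
  stopifnot(inherits(config, "pipeline_config"))
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  warn <- character(0)
  if (nrow(cohort) < 50)
    warn <- c(warn, sprintf("small sample (n = %d): bootstrap intervals %s",
                            nrow(cohort), "may be unreliable"))
  eng <- boot_engine(cohort, config, B, seed,
                     function(dat, cfg, ds)
                       flatten_disparity(fit_and_estimate(dat, cfg, ds)))
  qs <- apply(eng$reps, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  nm <- names(eng$point)
  parts <- regmatches(nm, regexpr("_[0-9]+$", nm))
  out <- data.frame(
    estimand = sub("_[0-9]+$", "", nm),
    contrast = as.integer(sub("^_", "", parts)),
    estimate = unname(eng$point),
    lower = qs[1, ], upper = qs[2, ])
  rownames(out) <- NULL
  structure(out, class = c("bootstrap_result", "data.frame"),
            B = B, failed = eng$failed, seed = seed, warnings = warn,
            replicates = eng$reps)
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf("Percentile bootstrap (B = %d, %d failed replicates)\n",
              attr(x, "B"), attr(x, "failed")))
  for (w in attr(x, "warnings")) cat("  warning:", w, "\n")
  df <- as.data.frame(x)
  df[c("estimate", "lower", "upper")] <-
    round(df[c("estimate", "lower", "upper")], digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
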
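#' Configuration for the disparity estimands
#'
#' @param K Monte-Carlo expansion factor: number of mediator draws per
#'   analysis row (default 1000).
#' @param reference Reference exposure level (default quintile 1, lowest
#'   genetic liability).
#' @param adj_ta_mode `"marginal"` (default): the Adj-TA is computed from a
#'   separate marginal outcome model E(Y | X, C).  `"integrated"`: it is
#'   obtained from the conditional outcome model by integrating the mediator
#'   over its fitted distribution at the index exposure level; kept for
#'   internal-consistency checking.
#' @param standardize `"pooled"` (default) standardises every contrast over
#'   the empirical confounder distribution of the full analysis sample;
#'   `"stratified"` uses the confounder rows of the index exposure stratum.
#' @param truncate_draws Left-truncate mediator draws at zero (default
#'   `TRUE`).
#' @param seed Integer seed for the mediator draws.
#' @return An object of class `estimand_config`.
#' @export
estimand_config <- function(K = 1000L, reference = 1L,
                            adj_ta_mode = c("marginal", "integrated"),
                            standardize = c("pooled", "stratified"),
                            truncate_draws = TRUE, seed = 1L) {
  check_scalar(K, "K", positive = TRUE, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(K = as.integer(K), reference = reference,
                 adj_ta_mode = match.arg(adj_ta_mode),
                 standardize = match.arg(standardize),
                 truncate_draws = isTRUE(truncate_draws),
                 seed = as.integer(seed)),
            class = "estimand_config")
}

# Rows of `cohort` complete on every variable used by the supplied specs
# (responses included): the pipeline-level analysis sample.
analysis_rows <- function(cohort, specs) {
  vars <- unique(unlist(lapply(specs, function(s) c(s$response, s$vars))))
  vars <- intersect(vars, names(cohort))
  which(complete.cases(cohort[, vars, drop = FALSE]))
}

# Linear predictor decomposed as a polynomial in the mediator:
# eta(X = level, M = m, C = c_i) = sum_d coefs[i, d+1] * m^d.
# Obtained exactly by evaluating the design at degree+1 mediator grid points
# and solving the (tiny) Vandermonde system; every formula_spec term is
# polynomial in the mediator, so this is exact, not an approximation.
eta_poly_coefs <- function(model, data, level, degree) {
  grid <- 0:degree
  etas <- vapply(grid, function(g)
    predict_mean(model, data, exposure_level = level, mediator_value = g),
    numeric(nrow(data)))
  if (degree == 0L) return(matrix(etas, ncol = 1L))
  V <- outer(grid, 0:degree, `^`)
  etas %*% t(solve(V))
}

check_exposure_levels <- function(model, reference) {
  lv <- model$levels$exposure
  if (is.null(lv))
    stop(sprintf("the %s model contains no exposure term",
                 model$spec$response), call. = FALSE)
  if (!reference %in% lv)
    stop(sprintf("reference level '%s' not among fitted exposure levels (%s)",
                 reference, paste(lv, collapse = ", ")), call. = FALSE)
  lv
}

std_rows <- function(cohort, rows, config, level) {
  if (config$standardize == "pooled") return(rows)
  rows[cohort$exposure_quintile[rows] == level]
}

#' Adjusted total association per exposure contrast
#'
#' Adj-TA_j is the confounder-standardised difference in expected outcome
#' between exposure level j and the reference level, with no intervention on
#' the mediator: the empirical mean over analysis-sample confounder rows of
#' the model's predicted difference.  The empirical mean realises the
#' standardisation sum over Pr(C = c) and extends it to continuous
#' confounders.
#'
#' @param cohort A cohort data frame.
#' @param outcome_model A marginal [fit_outcome_model()] (no mediator term)
#'   when `config$adj_ta_mode = "marginal"`; the conditional model when
#'   `"integrated"`.
#' @param mediator_model Required for the `"integrated"` mode only.
#' @param config An [estimand_config()].
#' @return Named numeric vector of Adj-TA_j, one per non-reference exposure
#'   level (kg/m^2).
#' @export
estimate_adj_ta <- function(cohort, outcome_model, config = estimand_config(),
                            mediator_model = NULL) {
  stopifnot(inherits(outcome_model, "outcome_model"),
            inherits(config, "estimand_config"))
  lv <- check_exposure_levels(outcome_model, config$reference)
  contrasts <- setdiff(lv, config$reference)

  if (config$adj_ta_mode == "marginal") {
    if (isTRUE(outcome_model$conditional))
      stop("marginal Adj-TA mode requires an outcome model without a ",
           "mediator term", call. = FALSE)
    rows <- analysis_rows(cohort, list(outcome_model$spec))
    pred_ref_all <- predict_mean(outcome_model, cohort[rows, , drop = FALSE],
                                 exposure_level = config$reference)
    out <- vapply(contrasts, function(j) {
      use <- std_rows(cohort, rows, config, j)
      dat <- cohort[use, , drop = FALSE]
      mean(predict_mean(outcome_model, dat, exposure_level = j) -
             predict_mean(outcome_model, dat,
                          exposure_level = config$reference))
    }, numeric(1))
    return(setNames(out, contrasts))
  }

  # integrated mode: E(Y | X = j, C) recovered from the conditional model by
  # integrating the mediator over its fitted distribution at X = j
  if (!isTRUE(outcome_model$conditional))
    stop("integrated Adj-TA mode requires the conditional outcome model",
         call. = FALSE)
  if (is.null(mediator_model))
    stop("integrated Adj-TA mode requires the mediator model", call. = FALSE)
  rows <- analysis_rows(cohort, list(outcome_model$spec,
                                     mediator_model$spec))
  degree <- mediator_degree(outcome_model$spec)
  level_mean <- function(j, use) {
    dat <- cohort[use, , drop = FALSE]
    mom <- mediator_draw_moments(mediator_model, dat, j, config$K,
                                 config$seed, config$truncate_draws, degree)
    cf <- eta_poly_coefs(outcome_model, dat, j, degree)
    mean(cf[, 1] + rowSums(cf[, -1, drop = FALSE] * mom))
  }
  out <- vapply(contrasts, function(j) {
    use <- std_rows(cohort, rows, config, j)
    level_mean(j, use) - level_mean(config$reference, use)
  }, numeric(1))
  setNames(out, contrasts)
}

# Shared IDM-DE core.  Mediator draws are taken at the reference exposure
# level and the identical draws evaluate both arms of every contrast
# (common random numbers).
idm_core <- function(cohort, mediator_model, outcome_model, config,
                     method = c("moments", "draws"), se = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(mediator_model, "mediator_model"),
            inherits(outcome_model, "outcome_model"),
            inherits(config, "estimand_config"))
  if (!isTRUE(outcome_model$conditional))
    stop("IDM-DE requires the conditional outcome model (with the mediator)",
         call. = FALSE)
  lv <- check_exposure_levels(outcome_model, config$reference)
  lv_med <- check_exposure_levels(mediator_model, config$reference)
  if (!identical(lv, lv_med))
    stop(sprintf(paste0("mediator and outcome models disagree on exposure ",
                        "levels: (%s) vs (%s)"),
                 paste(lv_med, collapse = ","), paste(lv, collapse = ",")),
         call. = FALSE)
  extra <- setdiff(outcome_model$spec$vars,
                   c(outcome_model$spec$exposure, outcome_model$spec$mediator,
                     names(cohort)))
  if (length(extra))
    stop("outcome model covariates absent from cohort: ",
         paste(extra, collapse = ", "), call. = FALSE)

  contrasts <- setdiff(lv, config$reference)
  rows <- analysis_rows(cohort, list(mediator_model$spec,
                                     outcome_model$spec))
  degree <- mediator_degree(outcome_model$spec)

  level_value <- function(use, mom_list) {
    dat <- cohort[use, , drop = FALSE]
    sapply(lv, function(l) {
      cf <- eta_poly_coefs(outcome_model, dat, l, degree)
      cf[, 1] + rowSums(cf[, -1, drop = FALSE] * mom_list)
    }, simplify = FALSE)
  }

  if (config$standardize == "pooled") {
    dat <- cohort[rows, , drop = FALSE]
    if (method == "moments" && !se) {
      mom <- mediator_draw_moments(mediator_model, dat, config$reference,
                                   config$K, config$seed,
                                   config$truncate_draws, degree)
      preds <- sapply(as.character(lv), function(l) {
        cf <- eta_poly_coefs(outcome_model, dat, as_level(l, lv), degree)
        mean(cf[, 1] + rowSums(cf[, -1, drop = FALSE] * mom))
      })
      est <- preds[as.character(contrasts)] -
        preds[as.character(config$reference)]
      return(list(estimate = setNames(unname(est), contrasts), mc_se = NULL,
                  n = nrow(dat)))
    }
    # draw-level path: per-draw estimates give the Monte-Carlo SE, and the
    # mean over draws is bit-identical to the moments path (same stream)
    M <- draw_mediator(mediator_model, dat, config$reference, config$K,
                       config$seed, truncate = config$truncate_draws)
    per_draw <- sapply(as.character(lv), function(l) {
      if (method == "draws") {
        # literal evaluation: rebuild the design at each draw column
        vapply(seq_len(config$K), function(k)
          mean(predict_mean(outcome_model, dat,
                            exposure_level = as_level(l, lv),
                            mediator_value = M[, k])), numeric(1))
      } else {
        cf <- eta_poly_coefs(outcome_model, dat, as_level(l, lv), degree)
        out <- rep(mean(cf[, 1]), config$K)
        Mp <- M
        for (d in seq_len(degree)) {
          if (d > 1) Mp <- Mp * M
          out <- out + colMeans(cf[, d + 1] * Mp)
        }
        out
      }
    })
    diff_draws <- per_draw[, as.character(contrasts), drop = FALSE] -
      per_draw[, as.character(config$reference)]
    est <- colMeans(diff_draws)
    mc_se <- apply(diff_draws, 2, sd) / sqrt(config$K)
    return(list(estimate = setNames(unname(est), contrasts),
                mc_se = setNames(unname(mc_se), contrasts), n = nrow(dat)))
  }

  # stratified standardisation: each contrast over its own stratum's C rows
  est <- vapply(contrasts, function(j) {
    use <- std_rows(cohort, rows, config, j)
    dat <- cohort[use, , drop = FALSE]
    mom <- mediator_draw_moments(mediator_model, dat, config$reference,
                                 config$K, config$seed,
                                 config$truncate_draws, degree)
    cf_j <- eta_poly_coefs(outcome_model, dat, j, degree)
    cf_r <- eta_poly_coefs(outcome_model, dat, config$reference, degree)
    mean((cf_j[, 1] - cf_r[, 1]) +
           rowSums((cf_j[, -1, drop = FALSE] -
                      cf_r[, -1, drop = FALSE]) * mom))
  }, numeric(1))
  list(estimate = setNames(est, contrasts), mc_se = NULL, n = length(rows))
}

as_level <- function(chr, lv) lv[match(chr, as.character(lv))]

#' Interventional disparity measure (direct effect) per exposure contrast
#'
#' IDM-DE_j is the exposure-outcome disparity that would remain if the
#' mediator's distribution were shifted to the one it has under the
#' reference (lowest-liability) exposure level: for each analysis row, `K`
#' mediator values are drawn from the fitted conditional distribution at the
#' reference level, the conditional outcome model is evaluated at exposure j
#' and at the reference with the *same* draws (common random numbers), and
#' the differences are averaged within and then across rows.
#'
#' @param cohort A cohort data frame.
#' @param mediator_model A fitted [fit_mediator_model()].
#' @param outcome_model The conditional [fit_outcome_model()] (must include
#'   the mediator).
#' @param config An [estimand_config()].
#' @param method `"moments"` (default) averages the polynomial-in-M linear
#'   predictor over the draws exactly via per-row draw moments; `"draws"`
#'   evaluates the model at every draw literally.  Both consume the same
#'   draw stream and give identical estimates.
#' @param se Also compute the Monte-Carlo standard error from the per-draw
#'   estimates (returned as attribute `"mc_se"`).
#' @return Named numeric vector of IDM-DE_j (kg/m^2), with attributes
#'   `"mc_se"` (if requested) and `"n"`.
#' @export
estimate_idm_de <- function(cohort, mediator_model, outcome_model,
                            config = estimand_config(),
                            method = c("moments", "draws"), se = FALSE) {
  res <- idm_core(cohort, mediator_model, outcome_model, config,
                  method = match.arg(method), se = se)
  structure(res$estimate, mc_se = res$mc_se, n = res$n)
}

#' IDM-DE for a binary exposure
#'
#' The two-group special case: the exposure must take exactly two levels in
#' the fitted models and the single contrast (exposed vs reference) is
#' returned.  Definitionally equivalent to the multi-level estimator
#' restricted to two levels.
#'
#' @inheritParams estimate_idm_de
#' @return Length-1 named numeric (the exposed-vs-reference contrast).
#' @export
estimate_idm_de_binary <- function(cohort, mediator_model, outcome_model,
                                   config = estimand_config(reference = 0L),
                                   method = c("moments", "draws"),
                                   se = FALSE) {
  lv <- check_exposure_levels(outcome_model, config$reference)
  if (length(lv) != 2L)
    stop(sprintf("exposure is not binary: fitted levels are (%s)",
                 paste(lv, collapse = ", ")), call. = FALSE)
  estimate_idm_de(cohort, mediator_model, outcome_model, config,
                  method = match.arg(method), se = se)
}

#' Deterministic quadrature oracle for the IDM-DE
#'
#' Replaces the Monte-Carlo mediator draws by Gauss-Hermite quadrature over
#' the fitted (untruncated) normal mediator distribution at the reference
#' exposure level, with otherwise identical standardisation.  Because every
#' model term is polynomial in the mediator, the quadrature is exact, which
#' makes this the independent oracle for the Monte-Carlo estimator and the
#' noise-free integrator used inside the sensitivity root-finder.
#'
#' @inheritParams estimate_idm_de
#' @param nodes Number of Gauss-Hermite nodes (default 64).
#' @return Named numeric vector of IDM-DE_j.
#' @export
numeric_oracle <- function(cohort, mediator_model, outcome_model,
                           config = estimand_config(truncate_draws = FALSE),
                           nodes = 64L) {
  stopifnot(inherits(config, "estimand_config"))
  if (config$truncate_draws)
    stop("the quadrature oracle assumes full normal support; use a config ",
         "with truncate_draws = FALSE", call. = FALSE)
  lv <- check_exposure_levels(outcome_model, config$reference)
  contrasts <- setdiff(lv, config$reference)
  rows <- analysis_rows(cohort, list(mediator_model$spec,
                                     outcome_model$spec))
  degree <- mediator_degree(outcome_model$spec)
  gh <- pracma::gaussHermite(nodes)

  quad_moments <- function(dat) {
    mu <- predict_mean(mediator_model, dat,
                       exposure_level = config$reference)
    s <- mediator_model$sigma
    vapply(seq_len(degree), function(d) {
      nodes_mat <- outer(mu, sqrt(2) * s * gh$x, `+`)^d
      drop(nodes_mat %*% gh$w) / sqrt(pi)
    }, numeric(length(mu)))
  }

  if (config$standardize == "pooled") {
    dat <- cohort[rows, , drop = FALSE]
    mom <- quad_moments(dat)
    preds <- vapply(lv, function(l) {
      cf <- eta_poly_coefs(outcome_model, dat, l, degree)
      mean(cf[, 1] + rowSums(cf[, -1, drop = FALSE] * mom))
    }, numeric(1))
    est <- preds[match(contrasts, lv)] - preds[match(config$reference, lv)]
    return(setNames(unname(est), contrasts))
  }
  est <- vapply(contrasts, function(j) {
    use <- std_rows(cohort, rows, config, j)
    dat <- cohort[use, , drop = FALSE]
    mom <- quad_moments(dat)
    cf_j <- eta_poly_coefs(outcome_model, dat, j, degree)
    cf_r <- eta_poly_coefs(outcome_model, dat, config$reference, degree)
    mean((cf_j[, 1] - cf_r[, 1]) +
           rowSums((cf_j[, -1, drop = FALSE] - cf_r[, -1, drop = FALSE]) *
                     mom))
  }, numeric(1))
  setNames(est, contrasts)
}

#' Joint disparity estimate: Adj-TA, IDM-DE and their difference
#'
#' Runs both estimands on the same analysis sample and seed and returns the
#' per-contrast table; `difference = adj_ta - idm_de` is the portion of the
#' disparity removable by the hypothetical mediator shift.
#'
#' @inheritParams estimate_idm_de
#' @param outcome_model_marginal The marginal outcome model for the Adj-TA.
#' @return A `disparity_estimate` data frame (one row per contrast).
#' @export
estimate_disparity <- function(cohort, mediator_model, outcome_model,
                               outcome_model_marginal,
                               config = estimand_config()) {
  adj <- estimate_adj_ta(cohort, outcome_model_marginal, config)
  idm <- estimate_idm_de(cohort, mediator_model, outcome_model, config)
  stopifnot(identical(names(adj), names(idm)))
  new_disparity_estimate(contrast = as.integer(names(adj)),
                         adj_ta = unname(adj),
                         idm_de = unname(as.numeric(idm)),
                         reference = config$reference,
                         source = "plug-in", n = attr(idm, "n"),
                         K = config$K)
}
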
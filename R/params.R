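#' Structural parameters for a synthetic PGS--mediator--outcome cohort
#'
#' Defines the data-generating process the package's analysis assumes: child
#' sex, maternal education and maternal pre-pregnancy BMI are drawn first, a
#' continuous polygenic score (PGS) is drawn and categorised into empirical
#' quintiles, average daily minutes of moderate-to-vigorous physical activity
#' (the mediator) follow a linear model in the quintile and confounders with
#' Gaussian noise left-truncated at zero, and BMI (the outcome) follows a
#' linear model in quintile, mediator and confounders.  An optional latent
#' standard-normal confounder can load on both the mediator and the outcome to
#' emulate unmeasured mediator--outcome confounding.
#'
#' In the structural equations maternal BMI enters centred at its mean and
#' maternal education enters as the numeric level centred at 2, so the
#' intercepts are interpretable as means for a reference child.  The default
#' calibration produces association directions and effect magnitudes typical
#' of birth-cohort studies of genetic liability to adiposity: the PGS is
#' positively associated with BMI and negatively with physical activity, and
#' physical activity is negatively associated with BMI; the top-quintile
#' confounder-adjusted total association is about 3 kg/m^2 of which about
#' 0.45 kg/m^2 flows through the mediator.  These defaults are package
#' choices for demonstration and testing, not estimates from any real cohort.
#'
#' @param n Number of participants (positive integer).
#' @param confounders List with `sex_p` (probability of sex = 1), `edu_probs`
#'   (probabilities of the ordinal maternal-education levels, at least 2),
#'   `mbmi_mean` and `mbmi_sd` (maternal BMI, kg/m^2).
#' @param pgs Loadings of the centred confounders on the PGS
#'   (`sex`, `edu`, `mbmi`); all 0 by default, giving a standard-normal score.
#' @param mediator List with `intercept` (min/day), `alpha` (length-5 vector
#'   of per-quintile shifts in min/day, first element must be 0), confounder
#'   effects `sex`, `edu`, `mbmi`, optional `sex_mbmi` interaction, and
#'   residual SD `sigma` (> 0, or 0 for a degenerate noiseless cohort).
#' @param outcome List with `intercept` (kg/m^2), `beta` (length-5 vector of
#'   per-quintile shifts, first element 0), mediator effect `gamma`
#'   (kg/m^2 per min/day), confounder effects `sex`, `edu`, `mbmi`, optional
#'   `mbmi2` quadratic term, optional `med_sex`/`med_mbmi`
#'   mediator-confounder interactions, and residual SD `sigma`.
#' @param latent Length-2 numeric `c(m = , y = )`: loadings of an unobserved
#'   standard-normal confounder on mediator and outcome (both 0 by default).
#' @param seed Integer seed; generation is fully deterministic given the
#'   parameters and seed.
#'
#' @return An object of class `generating_params`.
#' @seealso [generate_cohort()], [closed_form_truth()],
#'   [latent_residual_correlation()]
#' @export
#' @examples
#' p <- generating_params(n = 500, seed = 7)
#' cohort <- generate_cohort(p)
#' closed_form_truth(p)
generating_params <- function(n,
                              confounders = list(),
                              pgs = list(),
                              mediator = list(),
                              outcome = list(),
                              latent = c(m = 0, y = 0),
                              seed = 1L) {
  check_scalar(n, "n", positive = TRUE, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)

  confounders <- utils::modifyList(
    list(sex_p = 0.5, edu_probs = c(0.25, 0.45, 0.30),
         mbmi_mean = 24, mbmi_sd = 4), confounders)
  pgs <- utils::modifyList(list(sex = 0, edu = 0, mbmi = 0), pgs)
  mediator <- utils::modifyList(
    list(intercept = 48, alpha = c(0, -2, -4, -6, -9),
         sex = 6, edu = 1, mbmi = -0.2, sex_mbmi = 0, sigma = 8), mediator)
  outcome <- utils::modifyList(
    list(intercept = 19.4, beta = c(0, 0.7, 1.3, 1.9, 2.55), gamma = -0.05,
         sex = 0.3, edu = -0.3, mbmi = 0.15, mbmi2 = 0,
         med_sex = 0, med_mbmi = 0, sigma = 2.5), outcome)

  if (confounders$sex_p <= 0 || confounders$sex_p >= 1)
    stop_field("confounders$sex_p", "must lie in (0, 1)")
  if (length(confounders$edu_probs) < 2 || any(confounders$edu_probs < 0) ||
      abs(sum(confounders$edu_probs) - 1) > 1e-8)
    stop_field("confounders$edu_probs",
               "must be >= 2 non-negative probabilities summing to 1")
  check_scalar(confounders$mbmi_sd, "confounders$mbmi_sd", positive = TRUE)
  if (length(mediator$alpha) != 5 || mediator$alpha[1] != 0)
    stop_field("mediator$alpha",
               "must have length 5 with reference shift alpha_1 = 0")
  if (length(outcome$beta) != 5 || outcome$beta[1] != 0)
    stop_field("outcome$beta",
               "must have length 5 with reference shift beta_1 = 0")
  if (mediator$sigma < 0) stop_field("mediator$sigma", "must be >= 0")
  if (outcome$sigma < 0) stop_field("outcome$sigma", "must be >= 0")
  if (length(latent) != 2) stop_field("latent", "must be c(m = , y = )")
  latent <- c(m = unname(latent[[1]]), y = unname(latent[[2]]))

  structure(
    list(n = as.integer(n), confounders = confounders, pgs = pgs,
         mediator = mediator, outcome = outcome, latent = latent,
         seed = as.integer(seed)),
    class = "generating_params")
}

#' @export
print.generating_params <- function(x, ...) {
  cat("Synthetic cohort generating parameters\n")
  cat("  n:", x$n, " seed:", x$seed, "\n")
  cat("  mediator quintile shifts (min/day):",
      paste(x$mediator$alpha, collapse = ", "), "\n")
  cat("  outcome quintile shifts (kg/m^2):",
      paste(x$outcome$beta, collapse = ", "), "\n")
  cat("  mediator effect on outcome gamma:", x$outcome$gamma, "\n")
  cat("  latent confounder loadings (m, y):",
      paste(x$latent, collapse = ", "), "\n")
  invisible(x)
}

# TRUE when mediator and outcome equations are linear with no interaction or
# quadratic terms and no confounder loading on the PGS: the regime in which
# the closed-form estimands are valid.
is_linear_params <- function(params) {
  all(unlist(params$pgs) == 0) &&
    params$mediator$sex_mbmi == 0 &&
    params$outcome$mbmi2 == 0 &&
    params$outcome$med_sex == 0 &&
    params$outcome$med_mbmi == 0
}

# Exact P(M < 0) before truncation: mixture over sex x education x quintile
# cells of normal tail probabilities (maternal BMI and the latent confounder
# fold into the cell SD).  Requires linear params.
mediator_truncation_prob <- function(params) {
  cf <- params$confounders
  med <- params$mediator
  sd_cell <- sqrt(med$sigma^2 + (med$mbmi * cf$mbmi_sd)^2 +
                    params$latent[["m"]]^2)
  levels_edu <- seq_along(cf$edu_probs)
  p <- 0
  for (q in 1:5) for (s in 0:1) for (e in levels_edu) {
    mu <- med$intercept + med$alpha[q] + med$sex * s + med$edu * (e - 2)
    w <- 0.2 * (if (s == 1) cf$sex_p else 1 - cf$sex_p) * cf$edu_probs[e]
    tail_p <- if (sd_cell == 0) as.numeric(mu < 0) else pnorm(0, mu, sd_cell)
    p <- p + w * tail_p
  }
  p
}

#' Closed-form disparity estimands implied by linear generating parameters
#'
#' For a linear generating model with no interactions, no latent confounding
#' and negligible truncation, the confounder-standardised estimands have the
#' closed forms `Adj-TA_j = beta_j + gamma * alpha_j` and
#' `IDM-DE_j = beta_j`, so the disparity removable by shifting the mediator
#' distribution is `gamma * alpha_j`.  This serves as analytic ground truth
#' for validating the Monte-Carlo plug-in estimator.
#'
#' @param params A [generating_params()] object.  Must be linear (no
#'   interaction or quadratic terms, no latent confounder, no PGS loadings)
#'   with truncation probability `P(M < 0) < 1e-6`; otherwise the closed form
#'   is invalid and the function refuses.
#' @return A `disparity_estimate` data frame with one row per contrast
#'   (quintile 2..5 vs 1) and columns `contrast`, `adj_ta`, `idm_de`,
#'   `difference`.
#' @export
closed_form_truth <- function(params) {
  stopifnot(inherits(params, "generating_params"))
  if (!is_linear_params(params))
    stop("closed-form estimands are only valid for linear generating ",
         "parameters without interactions, quadratic terms or PGS loadings",
         call. = FALSE)
  if (any(params$latent != 0))
    stop("closed-form estimands require no latent confounder ",
         "(latent loadings must be 0)", call. = FALSE)
  p_trunc <- mediator_truncation_prob(params)
  if (p_trunc >= 1e-6)
    stop(sprintf(paste0("mediator truncation is not negligible under these ",
                        "parameters (P(M < 0) = %.2e >= 1e-6); the linear ",
                        "closed form is invalid"), p_trunc), call. = FALSE)
  alpha <- params$mediator$alpha[2:5]
  beta <- params$outcome$beta[2:5]
  gamma <- params$outcome$gamma
  new_disparity_estimate(contrast = 2:5,
                         adj_ta = beta + gamma * alpha,
                         idm_de = beta,
                         reference = 1L, source = "closed_form")
}

#' Residual mediator--outcome correlation induced by the latent confounder
#'
#' With latent loadings `(a, b)` on the mediator and outcome equations, the
#' correlation between the two equations' composite errors is
#' `a * b / sqrt((a^2 + sigma_M^2) * (b^2 + sigma_Y^2))`.  This is the
#' quantity the confounding sensitivity analysis tries to recover.
#'
#' @param params A [generating_params()] object.
#' @return The implied residual correlation (numeric scalar).
#' @seealso [latent_effects_for_rho()], [find_null_rho()]
#' @export
latent_residual_correlation <- function(params) {
  a <- params$latent[["m"]]; b <- params$latent[["y"]]
  a * b / sqrt((a^2 + params$mediator$sigma^2) *
                 (b^2 + params$outcome$sigma^2))
}

#' Latent-confounder loadings that induce a target residual correlation
#'
#' Solves for the outcome loading `b` such that, together with a chosen
#' mediator loading `a`, the latent confounder induces residual
#' mediator--outcome correlation `rho` (see
#' [latent_residual_correlation()]).  Used to calibrate recovery simulations
#' for the sensitivity analysis.
#'
#' @param params A [generating_params()] object supplying the residual SDs.
#' @param rho Target residual correlation in (-1, 1), non-zero.
#' @param effect_m Mediator loading `a` (min/day per SD of the latent
#'   confounder); must be large enough that `|rho| * sqrt(a^2 + sigma_M^2) / a
#'   < 1`.
#' @return Length-2 numeric `c(m = a, y = b)` suitable for the `latent`
#'   argument of [generating_params()].
#' @export
latent_effects_for_rho <- function(params, rho, effect_m = 2) {
  check_scalar(rho, "rho")
  if (abs(rho) >= 1 || rho == 0)
    stop_field("rho", "must be non-zero and inside (-1, 1)")
  check_scalar(effect_m, "effect_m", positive = TRUE)
  s_m_tot <- sqrt(effect_m^2 + params$mediator$sigma^2)
  r <- rho * s_m_tot / effect_m
  if (abs(r) >= 1)
    stop_field("effect_m", "too small to induce the requested correlation")
  b <- sign(r) * sqrt(r^2 * params$outcome$sigma^2 / (1 - r^2))
  c(m = effect_m, y = b)
}

new_disparity_estimate <- function(contrast, adj_ta, idm_de,
                                   reference, source, n = NA_integer_,
                                   K = NA_integer_) {
  out <- data.frame(contrast = contrast, adj_ta = adj_ta, idm_de = idm_de,
                    difference = adj_ta - idm_de)
  rownames(out) <- NULL
  structure(out, class = c("disparity_estimate", "data.frame"),
            reference = reference, source = source, n = n, K = K)
}

#' @export
print.disparity_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Disparity estimates (reference level %s, source: %s)\n",
              attr(x, "reference"), attr(x, "source")))
  if (!is.na(attr(x, "n")))
    cat(sprintf("  n analysed: %d   K: %s\n", attr(x, "n"),
                format(attr(x, "K"))))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- round(df[num], digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
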
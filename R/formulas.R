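#' Structured formula specification for the working models
#'
#' The plug-in estimator needs three parametric working models: the mediator
#' model f(M | X, C), the conditional outcome model E(Y | X, M, C) and the
#' marginal outcome model E(Y | X, C).  A `formula_spec` describes one of
#' them as an additive combination of exposure dummies (against the reference
#' quintile), confounder main effects, optional polynomial terms and optional
#' pairwise interactions.  Every term is polynomial in the mediator, which
#' the estimation code exploits to average predictions over mediator draws
#' exactly via draw moments.
#'
#' @param response Response column name.
#' @param exposure Exposure column name (entered as dummies against the
#'   lowest level), or `NULL` to omit the exposure.
#' @param confounders Character vector of confounder main effects.
#' @param mediator Mediator column name, or `NULL` for models without the
#'   mediator (the marginal outcome model and the mediator model itself).
#' @param factors Which of the variables are unordered categorical and enter
#'   as dummies (default `"maternal_education"`).
#' @param poly Named list `variable = degree`; adds `variable^k` terms for
#'   `k = 2..degree`.
#' @param interactions List of length-2 character vectors naming variable
#'   pairs whose product terms are included (e.g. `c("mediator", "sex")`).
#' @return An object of class `formula_spec`.
#' @seealso [default_formula_specs()], [fit_mediator_model()],
#'   [fit_outcome_model()]
#' @export
formula_spec <- function(response,
                         exposure = "exposure_quintile",
                         confounders = c("sex", "maternal_education",
                                         "maternal_bmi"),
                         mediator = NULL,
                         factors = "maternal_education",
                         poly = list(),
                         interactions = list()) {
  stopifnot(is.character(response), length(response) == 1L)
  vars <- unique(c(exposure, mediator, confounders))
  for (v in names(poly)) {
    if (!v %in% vars) stop_field("poly", sprintf("unknown variable '%s'", v))
    check_scalar(poly[[v]], paste0("poly$", v), positive = TRUE,
                 integer = TRUE)
    if (poly[[v]] < 2) stop_field("poly", "degrees below 2 are implicit")
  }
  for (pair in interactions) {
    if (length(pair) != 2L || !all(pair %in% vars))
      stop_field("interactions",
                 "each entry must name two variables used by the model")
  }
  if (response %in% vars)
    stop_field("response", "may not also appear as a predictor")
  structure(
    list(response = response, exposure = exposure, confounders = confounders,
         mediator = mediator, factors = intersect(factors, vars),
         poly = poly, interactions = interactions, vars = vars),
    class = "formula_spec")
}

#' @export
print.formula_spec <- function(x, ...) {
  rhs <- c(if (!is.null(x$exposure)) paste0("dummies(", x$exposure, ")"),
           x$mediator, x$confounders,
           unlist(lapply(names(x$poly), function(v)
             paste0(v, "^", 2:x$poly[[v]]))),
           vapply(x$interactions, paste, "", collapse = ":"))
  cat(x$response, "~", paste(rhs, collapse = " + "), "\n")
  invisible(x)
}

#' Default working-model specifications
#'
#' The package default mirrors a deliberately general parametric
#' specification: exposure quintile dummies and confounder main effects in
#' all three models, a maternal-BMI quadratic term in the mediator and both
#' outcome models, and mediator-by-sex and mediator-by-maternal-BMI
#' interactions in the conditional outcome model.
#'
#' @param interactions Logical; include the mediator-confounder interaction
#'   terms in the conditional outcome model (default `TRUE`).  The
#'   confounding sensitivity analysis requires a conditional model that is
#'   linear in the mediator with a single mediator coefficient, i.e.
#'   `interactions = FALSE`.
#' @return Named list with elements `mediator`, `outcome_conditional`,
#'   `outcome_marginal`.
#' @export
default_formula_specs <- function(interactions = TRUE) {
  med_int <- if (interactions)
    list(c("mediator", "sex"), c("mediator", "maternal_bmi")) else list()
  list(
    mediator = formula_spec("mediator", poly = list(maternal_bmi = 2)),
    outcome_conditional = formula_spec("outcome", mediator = "mediator",
                                       poly = list(maternal_bmi = 2),
                                       interactions = med_int),
    outcome_marginal = formula_spec("outcome",
                                    poly = list(maternal_bmi = 2)))
}

# ---- design construction ---------------------------------------------------
# Designs are built directly from the spec by cbind-ing computed columns:
# this is much faster than model.matrix() in the bootstrap hot loop and
# allows forcing the exposure arm and the mediator value without refactoring
# a model frame.

# Expand one variable into its column block.  `levels_info` carries the
# factor/exposure level sets recorded at fit time so that prediction designs
# are conformable with the fit.
var_columns <- function(v, spec, data, levels_info,
                        exposure_override, mediator_override, n) {
  if (!is.null(spec$exposure) && v == spec$exposure) {
    lv <- levels_info$exposure
    x <- exposure_override %||% data[[v]]
    cols <- lapply(lv[-1], function(l) as.numeric(x == l))
    names(cols) <- paste0(v, lv[-1])
    return(cols)
  }
  if (!is.null(spec$mediator) && v == spec$mediator &&
      !is.null(mediator_override)) {
    x <- rep_len(as.numeric(mediator_override), n)
    return(setNames(list(x), v))
  }
  x <- data[[v]]
  if (v %in% spec$factors) {
    lv <- levels_info$factors[[v]]
    cols <- lapply(lv[-1], function(l) as.numeric(x == l))
    names(cols) <- paste0(v, lv[-1])
    return(cols)
  }
  setNames(list(as.numeric(x)), v)
}

build_design <- function(spec, data, levels_info,
                         exposure_override = NULL, mediator_override = NULL) {
  n <- nrow(data)
  for (v in spec$vars) {
    skip_na <- (!is.null(spec$exposure) && v == spec$exposure &&
                  !is.null(exposure_override)) ||
      (!is.null(spec$mediator) && v == spec$mediator &&
         !is.null(mediator_override))
    if (skip_na) next
    if (!v %in% names(data))
      stop(sprintf("variable '%s' required by the model is absent", v),
           call. = FALSE)
    if (anyNA(data[[v]]))
      stop(sprintf("variable '%s' has missing values in rows %s",
                   v, paste(utils::head(which(is.na(data[[v]])), 5),
                            collapse = ", ")), call. = FALSE)
  }
  cols <- list("(Intercept)" = rep(1, n))
  for (v in c(spec$exposure, spec$mediator, spec$confounders)) {
    cols <- c(cols, var_columns(v, spec, data, levels_info,
                                exposure_override, mediator_override, n))
  }
  for (v in names(spec$poly)) {
    base <- var_columns(v, spec, data, levels_info,
                        exposure_override, mediator_override, n)[[1]]
    for (k in 2:spec$poly[[v]])
      cols[[paste0(v, "^", k)]] <- base^k
  }
  for (pair in spec$interactions) {
    a <- var_columns(pair[1], spec, data, levels_info,
                     exposure_override, mediator_override, n)
    b <- var_columns(pair[2], spec, data, levels_info,
                     exposure_override, mediator_override, n)
    for (i in seq_along(a)) for (j in seq_along(b))
      cols[[paste(names(a)[i], names(b)[j], sep = ":")]] <- a[[i]] * b[[j]]
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  mat
}

# Level sets used to build dummies, recorded from the fitting data.
record_levels <- function(spec, data) {
  out <- list(factors = list())
  if (!is.null(spec$exposure))
    out$exposure <- sort(unique(data[[spec$exposure]]))
  for (v in spec$factors)
    out$factors[[v]] <- sort(unique(data[[v]]))
  out
}

# Highest power in which the mediator enters the linear predictor.
mediator_degree <- function(spec) {
  if (is.null(spec$mediator)) return(0L)
  max(1L, spec$poly[[spec$mediator]] %||% 1L)
}
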
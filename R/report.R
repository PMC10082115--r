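#' Per-quintile descriptive summary of a cohort
#'
#' Means, SDs and counts of the mediator and outcome within each exposure
#' quintile, plus the pairwise correlations of PGS, mediator and outcome on
#' complete pairs.  An empty quintile is reported with count 0 and missing
#' cells; a constant variable yields an undefined (missing) correlation,
#' never zero.
#'
#' @param cohort A cohort data frame.
#' @return A list with `by_quintile` (data frame) and `correlations`
#'   (named numeric).
#' @export
summarize_associations <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  qs <- 1:5
  cell <- function(q, v, f) {
    x <- cohort[[v]][cohort$exposure_quintile == q]
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else f(x)
  }
  by_q <- data.frame(
    quintile = qs,
    n = vapply(qs, function(q)
      sum(cohort$exposure_quintile == q, na.rm = TRUE), numeric(1)),
    mediator_mean = vapply(qs, cell, numeric(1), v = "mediator", f = mean),
    mediator_sd = vapply(qs, cell, numeric(1), v = "mediator", f = sd),
    outcome_mean = vapply(qs, cell, numeric(1), v = "outcome", f = mean),
    outcome_sd = vapply(qs, cell, numeric(1), v = "outcome", f = sd))
  safe_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }
  cors <- c(pgs_mediator = safe_cor(cohort$pgs, cohort$mediator),
            pgs_outcome = safe_cor(cohort$pgs, cohort$outcome),
            mediator_outcome = safe_cor(cohort$mediator, cohort$outcome))
  list(by_quintile = by_q, correlations = cors)
}

#' Packaged demonstration configuration
#'
#' A complete [pipeline_config()] using the calibrated synthetic cohort:
#' n participants, MAR missingness concentrated in the mediator and outcome,
#' chained-equation imputation as the sensitivity analysis, and the
#' confounding sensitivity stage.  The default cohort size matches the
#' scale of the birth-cohort samples this design emulates (about 6000
#' children).  Scaled-down defaults (`K = 200`, `B = 200`) keep a laptop
#' run short; the headline analysis settings are `K = 1000`, `B = 1000`.
#'
#' @param n Cohort size (default 6000).
#' @param K Monte-Carlo expansion factor.
#' @param B Bootstrap replicates.
#' @param seed Master seed.
#' @param output_dir Optional output directory.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(n = 6000L, K = 200L, B = 200L, seed = 1L,
                                 output_dir = NULL) {
  pipeline_config(
    params = generating_params(n = n, seed = derive_seed(seed, 101)),
    formulas = default_formula_specs(),
    estimand = estimand_config(K = K, seed = derive_seed(seed, 102)),
    missingness = missingness_spec(
      list(mediator = list(rate = 0.25,
                           coefs = c(maternal_bmi = 0.10, outcome = 0.10)),
           outcome = list(rate = 0.10, coefs = c(maternal_bmi = 0.05))),
      seed = derive_seed(seed, 103)),
    imputation = imputation_spec(seed = derive_seed(seed, 104)),
    B = B, output_dir = output_dir, seed = seed)
}

stage <- function(log, name, expr) {
  log(sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  log(sprintf("stage %s: done", name))
  res
}

#' Run the complete disparity analysis workflow
#'
#' Executes: cohort load/simulation (with optional MAR missingness), the
#' complete-case primary analysis with percentile bootstrap intervals, the
#' optional imputed-data sensitivity analysis (imputation redone inside each
#' bootstrap replicate), and the unmeasured-confounding sensitivity
#' analysis.  When `config$output_dir` is set, writes the cohort CSV, one
#' results CSV per analysis (one row per contrast: `contrast`, `adj_ta`,
#' `idm_de`, `difference`, each with bootstrap bounds), the sensitivity
#' curve CSV, a JSON metadata file (seeds, sample sizes, package version,
#' config hash) and a plain-text log.  Outputs are byte-reproducible given
#' the master seed; partial outputs are removed if a stage fails.
#'
#' @param config A [pipeline_config()].
#' @return A list with elements `cohort`, `complete_case`
#'   (`bootstrap_result`), `imputed` (or `NULL`), `sensitivity` (or `NULL`),
#'   `descriptives` and `log`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  outdir <- config$output_dir
  written <- character(0)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }

  tryCatch({
    cohort <- stage(log, "load", {
      if (!is.null(config$input)) {
        x <- read_cohort(config$input)
        log(sprintf("  read %d rows from %s", nrow(x), config$input))
        x
      } else {
        x <- generate_cohort(config$params)
        log(sprintf("  simulated %d rows (seed %d)", nrow(x),
                    config$params$seed))
        if (!is.null(config$missingness)) {
          x <- induce_missingness(x, config$missingness)
          log(sprintf("  induced missingness: %s",
                      paste(sprintf("%s %.1f%%", names(x)[colSums(is.na(x)) > 0],
                                    100 * colMeans(is.na(x))[colSums(is.na(x)) > 0]),
                            collapse = ", ")))
        }
        x
      }
    })

    desc <- stage(log, "describe", summarize_associations(cohort))

    cc_config <- config
    cc_config$imputation <- NULL
    complete_case <- stage(log, "complete-case analysis", {
      res <- bootstrap_pipeline(cohort, cc_config, B = config$B,
                                seed = derive_seed(config$seed, 1))
      log(sprintf("  complete cases analysed: %d of %d",
                  sum(complete.cases(cohort)), nrow(cohort)))
      res
    })

    imputed <- NULL
    if (!is.null(config$imputation)) {
      imputed <- stage(log, "imputed analysis", {
        bootstrap_pipeline(cohort, config, B = config$B,
                           seed = derive_seed(config$seed, 2))
      })
    }

    sens <- NULL
    if (!is.null(config$sensitivity)) {
      sens <- stage(log, "confounding sensitivity", {
        scfg <- cc_config
        scfg$formulas <- default_formula_specs(interactions = FALSE)
        find_null_rho(cohort, scfg,
                      contrast = config$sensitivity$contrast %||% 5L,
                      grid = config$sensitivity$grid %||%
                        seq(-0.5, 0.5, length.out = 41),
                      B = config$sensitivity$B %||% 0L,
                      seed = derive_seed(config$seed, 3))
      })
    }

    if (!is.null(outdir)) {
      w <- function(path) {
        written <<- c(written, path)
        path
      }
      write_cohort(cohort, w(file.path(outdir, "cohort.csv")),
                   seed = config$seed)
      written <- c(written, file.path(outdir, "cohort.csv.meta.json"))
      write_results_csv(complete_case,
                        w(file.path(outdir, "results_complete_case.csv")))
      jsonlite::write_json(as.data.frame(complete_case),
                           w(file.path(outdir,
                                       "results_complete_case.json")),
                           digits = NA)
      if (!is.null(imputed))
        write_results_csv(imputed,
                          w(file.path(outdir, "results_imputed.csv")))
      if (!is.null(sens))
        write.csv(sens$curve,
                  w(file.path(outdir, "sensitivity_grid.csv")),
                  row.names = FALSE)
      meta <- list(
        master_seed = config$seed,
        config_hash = config_hash(config[setdiff(names(config),
                                                 "output_dir")]),
        package_version = as.character(packageVersion("pgsdisparity")),
        n_cohort = nrow(cohort),
        n_complete_case = sum(complete.cases(cohort)),
        B = config$B, K = config$estimand$K,
        rho_star = if (!is.null(sens)) sens$rho_star else NULL)
      jsonlite::write_json(meta, w(file.path(outdir, "metadata.json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
      writeLines(log_lines, w(file.path(outdir, "log.txt")))
    }

    list(cohort = cohort, complete_case = complete_case, imputed = imputed,
         sensitivity = sens, descriptives = desc, log = log_lines)
  }, error = on_fail)
}

# One row per contrast with point estimates and bootstrap bounds, mirroring
# a per-contrast results table.
write_results_csv <- function(boot, path) {
  wide <- NULL
  for (e in unique(boot$estimand)) {
    part <- boot[boot$estimand == e, c("contrast", "estimate", "lower",
                                       "upper")]
    names(part) <- c("contrast", e, paste0(e, "_lower"), paste0(e, "_upper"))
    wide <- if (is.null(wide)) part else merge(wide, part, by = "contrast")
  }
  write.csv(wide[order(wide$contrast), ], path, row.names = FALSE)
  invisible(path)
}
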
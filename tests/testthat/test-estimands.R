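test_that("estimand identities: zero-coefficient null, difference identity,
           permutation invariance", {
  p <- generating_params(n = 3000, seed = 201)
  s <- fitted_setup(p)
  cfg <- estimand_config(K = 100, seed = 5)

  # zeroed exposure coefficients force Adj-TA = 0 exactly
  null_marg <- s$marginal
  null_marg$coef[grep("^exposure_quintile", names(null_marg$coef))] <- 0
  expect_identical(unname(estimate_adj_ta(s$cohort, null_marg, cfg)),
                   rep(0, 4))
  # and a fully zeroed conditional model forces IDM-DE = 0 exactly
  null_cond <- s$conditional
  null_cond$coef[] <- 0
  expect_identical(unname(as.numeric(
    estimate_idm_de(s$cohort, s$mediator, null_cond, cfg))), rep(0, 4))

  # difference column is exactly Adj-TA - IDM-DE from separate runs
  est <- estimate_disparity(s$cohort, s$mediator, s$conditional,
                            s$marginal, cfg)
  adj <- estimate_adj_ta(s$cohort, s$marginal, cfg)
  idm <- estimate_idm_de(s$cohort, s$mediator, s$conditional, cfg)
  expect_identical(est$difference, est$adj_ta - est$idm_de)
  expect_identical(est$adj_ta, unname(adj))
  expect_identical(est$idm_de, unname(as.numeric(idm)))

  # Adj-TA is an empirical mean over rows: invariant to row permutation
  perm <- s$cohort[sample(nrow(s$cohort)), ]
  expect_equal(estimate_adj_ta(perm, s$marginal, cfg), adj,
               tolerance = 1e-12)
})

test_that("moments and literal-draws evaluations are identical, including
           with exposure-mediator interactions", {
  p <- generating_params(n = 300, seed = 202)
  co <- generate_cohort(p)
  med <- fit_mediator_model(co, linear_specs()$mediator)
  cfg <- estimand_config(K = 40, seed = 7)

  spec_xm <- formula_spec("outcome", mediator = "mediator",
                          interactions = list(
                            c("mediator", "exposure_quintile"),
                            c("mediator", "sex")))
  oc_xm <- fit_outcome_model(co, spec_xm, TRUE)
  a <- estimate_idm_de(co, med, oc_xm, cfg, method = "moments")
  b <- estimate_idm_de(co, med, oc_xm, cfg, method = "draws")
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
  # the per-draw (SE) path shares the stream too
  d <- estimate_idm_de(co, med, oc_xm, cfg, se = TRUE)
  expect_equal(as.numeric(a), as.numeric(d), tolerance = 1e-12)
  expect_true(all(attr(d, "mc_se") > 0))  # draws genuinely matter here

  # without exposure-mediator coupling the common draws cancel exactly in
  # the contrast, so the Monte-Carlo SE is numerically zero
  oc_lin <- fit_outcome_model(co, linear_specs()$outcome_conditional, TRUE)
  d0 <- estimate_idm_de(co, med, oc_lin, cfg, se = TRUE)
  expect_true(all(attr(d0, "mc_se") < 1e-10))
})

test_that("Monte-Carlo dispersion scales as 1/K", {
  p <- generating_params(n = 300, seed = 203)
  co <- generate_cohort(p)
  med <- fit_mediator_model(co, linear_specs()$mediator)
  spec_xm <- formula_spec("outcome", mediator = "mediator",
                          interactions = list(
                            c("mediator", "exposure_quintile")))
  oc <- fit_outcome_model(co, spec_xm, TRUE)
  est_at <- function(K, seed)
    estimate_idm_de(co, med, oc, estimand_config(K = K, seed = seed))[["5"]]
  e1 <- vapply(1:40, function(r) est_at(1L, 300 + r), numeric(1))
  e25 <- vapply(1:40, function(r) est_at(25L, 700 + r), numeric(1))
  # identical expectation, variance ratio ~ K (loose factor-3 band)
  expect_lt(abs(mean(e1) - mean(e25)), 4 * sd(e1) / sqrt(40))
  ratio <- var(e1) / var(e25)
  expect_gt(ratio, 25 / 3)
  expect_lt(ratio, 25 * 3)
})

test_that("Adj-TA modes agree and gamma-free models make IDM-DE equal the
           integrated Adj-TA exactly", {
  p <- generating_params(n = 8000, seed = 204)
  s <- fitted_setup(p)
  cfg <- estimand_config(K = 200, seed = 3)
  adj_m <- estimate_adj_ta(s$cohort, s$marginal, cfg)
  cfg_i <- cfg
  cfg_i$adj_ta_mode <- "integrated"
  adj_i <- estimate_adj_ta(s$cohort, s$conditional, cfg_i,
                           mediator_model = s$mediator)
  ses <- s$marginal$se[paste0("exposure_quintile", 2:5)]
  expect_within_se(adj_i, adj_m, ses)

  # when the mediator does not enter the outcome model at all, the same
  # draws cancel and IDM-DE == integrated Adj-TA exactly
  gamma_free <- s$conditional
  gamma_free$coef[["mediator"]] <- 0
  idm <- estimate_idm_de(s$cohort, s$mediator, gamma_free, cfg)
  adj_g <- estimate_adj_ta(s$cohort, gamma_free, cfg_i,
                           mediator_model = s$mediator)
  expect_equal(as.numeric(idm), unname(adj_g), tolerance = 1e-12)

  # marginal mode refuses a model with a mediator term
  expect_error(estimate_adj_ta(s$cohort, s$conditional, cfg),
               "without a|mediator")
})

test_that("linear-truth cohorts are recovered within sampling error", {
  p <- generating_params(n = 6000, seed = 205)
  truth <- closed_form_truth(p)
  s <- fitted_setup(p)
  est <- estimate_disparity(s$cohort, s$mediator, s$conditional, s$marginal,
                            estimand_config(K = 150, seed = 8))
  se_m <- s$marginal$se[paste0("exposure_quintile", 2:5)]
  se_c <- s$conditional$se[paste0("exposure_quintile", 2:5)]
  expect_within_se(est$adj_ta, truth$adj_ta, se_m)
  expect_within_se(est$idm_de, truth$idm_de, se_c)
})

test_that("binary-exposure estimator matches the top-quintile contrast and
           validates its input", {
  p <- generating_params(n = 20000, seed = 206)
  s <- fitted_setup(p)
  cfg <- estimand_config(K = 200, seed = 4)
  idm5 <- estimate_idm_de(s$cohort, s$mediator, s$conditional, cfg)[["5"]]

  sub <- s$cohort[s$cohort$exposure_quintile %in% c(1, 5), ]
  sub$exposure_quintile <- ifelse(sub$exposure_quintile == 5, 1L, 0L)
  med_b <- fit_mediator_model(sub, linear_specs()$mediator)
  oc_b <- fit_outcome_model(sub, linear_specs()$outcome_conditional, TRUE)
  cfg_b <- estimand_config(K = 200, reference = 0L, seed = 4)
  idm_b <- estimate_idm_de_binary(sub, med_b, oc_b, cfg_b)
  se <- sqrt(s$conditional$se[["exposure_quintile5"]]^2 +
               oc_b$se[["exposure_quintile1"]]^2)
  expect_within_se(idm_b[["1"]], idm5, se)

  # zeroed model gives exactly zero
  oc0 <- oc_b
  oc0$coef[] <- 0
  expect_identical(unname(as.numeric(
    estimate_idm_de_binary(sub, med_b, oc0, cfg_b))), 0)

  # refuses a non-binary exposure
  expect_error(estimate_idm_de_binary(s$cohort, s$mediator, s$conditional,
                                      cfg), "not binary")
})

test_that("quadrature oracle is exact for polynomial mediator terms and
           refuses truncation", {
  p <- generating_params(n = 2000, seed = 207)
  s <- fitted_setup(p)
  cfg <- estimand_config(truncate_draws = FALSE, seed = 2)

  # linear case: oracle equals the exposure coefficients to 1e-10 relative
  orc <- numeric_oracle(s$cohort, s$mediator, s$conditional, cfg)
  beta_hat <- s$conditional$coef[paste0("exposure_quintile", 2:5)]
  expect_lt(max(abs(orc - beta_hat) / pmax(abs(beta_hat), 1)), 1e-10)

  # exposure-mediator interaction + quadratic mediator: compare against an
  # independent symbolic standardisation using E[M] = mu, E[M^2] = mu^2 +
  # sigma^2 under the fitted normal
  spec_q <- formula_spec("outcome", mediator = "mediator",
                         poly = list(mediator = 2),
                         interactions = list(
                           c("mediator", "exposure_quintile")))
  oc_q <- fit_outcome_model(s$cohort, spec_q, TRUE)
  orc_q <- numeric_oracle(s$cohort, s$mediator, oc_q, cfg)
  rows <- s$cohort[sort(intersect(s$mediator$rows_used, oc_q$rows_used)), ]
  mu <- predict_mean(s$mediator, rows, exposure_level = 1)
  sg <- s$mediator$sigma
  symbolic <- vapply(2:5, function(j) {
    eta_at <- function(lvl, m) predict_mean(oc_q, rows, exposure_level = lvl,
                                            mediator_value = m)
    # quadratic interpolation of the per-row linear predictor in m
    val <- function(lvl) {
      e0 <- eta_at(lvl, 0); e1 <- eta_at(lvl, 1); e2 <- eta_at(lvl, 2)
      D <- (e2 - 2 * e1 + e0) / 2
      B <- e1 - e0 - D
      mean(e0 + B * mu + D * (mu^2 + sg^2))
    }
    val(j) - val(1)
  }, numeric(1))
  expect_equal(unname(orc_q), symbolic, tolerance = 1e-10)

  expect_error(numeric_oracle(s$cohort, s$mediator, s$conditional,
                              estimand_config(truncate_draws = TRUE)),
               "truncate_draws")
})

test_that("null mediator pathways leave no removable disparity", {
  # no X -> M path: alpha = 0
  p <- generating_params(n = 4000, mediator = list(alpha = rep(0, 5)),
                         seed = 208)
  co <- generate_cohort(p)
  cfg <- linear_config(p, K = 150, B = 80, seed = 9)
  bs <- bootstrap_pipeline(co, cfg)
  d <- bs[bs$estimand == "difference", ]
  se <- (d$upper - d$lower) / (2 * 1.96)
  expect_within_se(d$estimate, 0, se)
})
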
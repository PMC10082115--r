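test_that("generation is deterministic and the noiseless case is exact", {
  p <- degenerate_params()
  co <- generate_cohort(p)
  expect_equal(nrow(co), 600L)
  expect_true(all(co$mediator == 30))
  expect_true(all(co$outcome == 18))

  p2 <- generating_params(n = 800, seed = 11)
  expect_identical(generate_cohort(p2), generate_cohort(p2))
  p3 <- generating_params(n = 800, seed = 12)
  expect_false(identical(generate_cohort(p2)$pgs, generate_cohort(p3)$pgs))

  expect_error(generating_params(n = 0), "n")
  expect_error(generating_params(n = 100,
                                 mediator = list(sigma = -1)), "sigma")
  expect_error(generating_params(n = 100,
                                 mediator = list(alpha = c(1, 0, 0, 0, 0))),
               "alpha")
})

test_that("default calibration shows the documented association structure", {
  p <- generating_params(n = 10000, seed = 21)
  co <- generate_cohort(p)
  cors <- summarize_associations(co)$correlations
  expect_gt(cors[["pgs_outcome"]], 0)
  expect_lt(cors[["pgs_mediator"]], 0)
  expect_lt(cors[["mediator_outcome"]], 0)

  # per-quintile mediator means: strictly decreasing, and matching a direct
  # brute-force average of the generating equation within simulation error
  med <- p$mediator
  cf <- p$confounders
  mu <- med$intercept + med$alpha[co$exposure_quintile] +
    med$sex * co$sex + med$edu * (co$maternal_education - 2) +
    med$mbmi * (co$maternal_bmi - cf$mbmi_mean)
  for (q in 1:5) {
    idx <- co$exposure_quintile == q
    expect_within_se(mean(co$mediator[idx]), mean(mu[idx]),
                     med$sigma / sqrt(sum(idx)))
  }
  qmeans <- summarize_associations(co)$by_quintile$mediator_mean
  expect_true(all(diff(qmeans) < 0))
})

test_that("simulated marginals match their analytic moments", {
  p <- generating_params(n = 10000, seed = 31)
  co <- generate_cohort(p)
  n <- nrow(co)
  expect_within_se(mean(co$sex), 0.5, sqrt(0.25 / n))
  expect_within_se(mean(co$maternal_bmi), 24, 4 / sqrt(n))
  expect_within_se(sd(co$maternal_bmi), 4, 4 / sqrt(2 * n))
  expect_within_se(mean(co$pgs), 0, 1 / sqrt(n))
  expect_within_se(sd(co$pgs), 1, 1 / sqrt(2 * n))
  # outcome mean: E[Y] = intercept + mean(beta) + gamma E[M] + sex effect
  m_mean <- mean(co$mediator)
  y_mean <- p$outcome$intercept + mean(p$outcome$beta) +
    p$outcome$gamma * m_mean + p$outcome$sex * 0.5
  expect_within_se(mean(co$outcome), y_mean,
                   sd(co$outcome) / sqrt(n))
})

test_that("latent confounder induces the closed-form residual correlation", {
  base <- generating_params(n = 10000, seed = 41)
  lat <- latent_effects_for_rho(base, -0.10, effect_m = 2)
  p <- generating_params(n = 10000, latent = lat, seed = 41)
  expect_equal(latent_residual_correlation(p), -0.10, tolerance = 1e-10)

  co <- generate_cohort(p)
  med <- p$mediator; out <- p$outcome; cf <- p$confounders
  mbmi_c <- co$maternal_bmi - cf$mbmi_mean
  edu_c <- co$maternal_education - 2
  res_m <- co$mediator - (med$intercept + med$alpha[co$exposure_quintile] +
                            med$sex * co$sex + med$edu * edu_c +
                            med$mbmi * mbmi_c)
  res_y <- co$outcome - (out$intercept + out$beta[co$exposure_quintile] +
                           out$gamma * co$mediator + out$sex * co$sex +
                           out$edu * edu_c + out$mbmi * mbmi_c)
  # res_y still contains gamma-free latent + noise; correlation of the two
  # structural errors should match the closed form within +/- 0.02
  expect_lt(abs(cor(res_m, res_y) - (-0.10)), 0.02)
})

test_that("quintile assignment is rank-based with lower-bin ties", {
  expect_identical(assign_quintiles(1:10),
                   as.integer(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)))
  x <- rnorm(10007)
  lab <- assign_quintiles(x)
  expect_identical(lab, assign_quintiles(exp(x / 3)))  # monotone invariance
  expect_true(all(table(lab) %in% c(2001L, 2002L)))
  # boundary tie goes to the lower quintile
  y <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9)
  expect_identical(assign_quintiles(y)[2:3], c(1L, 1L))
  expect_error(assign_quintiles(rep(1, 10)), "identical")
  expect_error(assign_quintiles(1:3), "at least")
  expect_error(assign_quintiles(c(1, NA, 2, 3, 4)), "missing")
})

test_that("missingness hits target rates and is MAR in the stated direction", {
  p <- generating_params(n = 5000, seed = 51)
  co <- generate_cohort(p)

  spec0 <- missingness_spec(list(mediator = list(rate = 0)), seed = 1)
  expect_identical(induce_missingness(co, spec0), co)

  spec <- missingness_spec(
    list(mediator = list(rate = 0.3, coefs = c(maternal_bmi = 0.15))),
    seed = 5)
  co_m <- induce_missingness(co, spec)
  n_obs <- sum(!is.na(co_m$mediator))
  expect_true(n_obs >= 3350 && n_obs <= 3650)  # binomial bound at 0.3
  expect_identical(co_m$outcome, co$outcome)   # non-target untouched
  expect_identical(induce_missingness(co, spec), co_m)  # deterministic

  # positive loading on maternal BMI: mothers of children with missing
  # mediator have higher BMI
  expect_gt(mean(co_m$maternal_bmi[is.na(co_m$mediator)]),
            mean(co_m$maternal_bmi[!is.na(co_m$mediator)]))

  expect_error(missingness_spec(
    list(mediator = list(rate = 0.2, coefs = c(mediator = 1)))),
    "self-masking")
  # predictors of missingness must be fully observed
  spec2 <- missingness_spec(
    list(outcome = list(rate = 0.2, coefs = c(mediator = 0.1))), seed = 2)
  expect_error(induce_missingness(co_m, spec2), "fully")
})

test_that("closed-form truth matches the estimand algebra and refuses
           out-of-domain parameters", {
  p0 <- generating_params(n = 100, outcome = list(gamma = 0), seed = 1)
  tr0 <- closed_form_truth(p0)
  expect_equal(tr0$adj_ta, tr0$idm_de)
  expect_equal(tr0$difference, rep(0, 4))

  p1 <- generating_params(n = 100,
                          mediator = list(alpha = rep(0, 5)), seed = 1)
  expect_equal(closed_form_truth(p1)$difference, rep(0, 4))

  p2 <- generating_params(n = 100, seed = 1)
  tr2 <- closed_form_truth(p2)
  expect_equal(tr2$difference[4], 0.45)  # gamma = -0.05, alpha_5 = -9
  expect_equal(tr2$adj_ta, tr2$idm_de + tr2$difference)

  expect_error(closed_form_truth(
    generating_params(n = 100, outcome = list(med_sex = 0.1))), "linear")
  expect_error(closed_form_truth(
    generating_params(n = 100, latent = c(m = 1, y = 1))), "latent")
  expect_error(closed_form_truth(
    generating_params(n = 100, mediator = list(intercept = 5))),
    "truncation")
})

test_that("closed-form truth agrees with a population Monte-Carlo
           evaluation of both standardisation formulas", {
  p <- generating_params(n = 400000, seed = 61)
  truth <- closed_form_truth(p)
  co <- generate_cohort(p)
  med <- p$mediator; out <- p$outcome; cf <- p$confounders
  mbmi_c <- co$maternal_bmi - cf$mbmi_mean
  edu_c <- co$maternal_education - 2
  # potential-outcome simulation straight from the structural equations:
  # mediator drawn at reference exposure, outcome mean evaluated per arm
  set.seed(62)
  m_ref <- med$intercept + med$alpha[1] + med$sex * co$sex +
    med$edu * edu_c + med$mbmi * mbmi_c + rnorm(nrow(co), 0, med$sigma)
  ey <- function(q, m) out$intercept + out$beta[q] + out$gamma * m +
    out$sex * co$sex + out$edu * edu_c + out$mbmi * mbmi_c
  for (j in 2:5) {
    idm_mc <- mean(ey(j, m_ref) - ey(1, m_ref))
    m_j <- med$intercept + med$alpha[j] + med$sex * co$sex +
      med$edu * edu_c + med$mbmi * mbmi_c
    m_1 <- m_j - med$alpha[j] + med$alpha[1]
    adj_mc <- mean(ey(j, m_j) - ey(1, m_1))
    mc_se <- sd(ey(j, m_ref) - ey(1, m_ref)) / sqrt(nrow(co))
    expect_within_se(idm_mc, truth$idm_de[j - 1], max(mc_se, 1e-8))
    expect_within_se(adj_mc, truth$adj_ta[j - 1], max(mc_se, 1e-8))
  }
})

test_that("cohort CSV and params YAML round-trip faithfully", {
  p <- generating_params(n = 300, seed = 71)
  co <- induce_missingness(
    generate_cohort(p),
    missingness_spec(list(mediator = list(rate = 0.2)), seed = 3))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path, seed = 71)
  back <- read_cohort(path)
  expect_equal(back$mediator, co$mediator)
  expect_equal(back$pgs, co$pgs, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".meta.json")))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 71)

  ypath <- tempfile(fileext = ".yaml")
  write_params(p, ypath)
  p2 <- read_params(ypath)
  expect_identical(generate_cohort(p2), generate_cohort(p))

  mspec <- missingness_spec(
    list(mediator = list(rate = 0.3, coefs = c(maternal_bmi = 0.1))),
    seed = 9)
  mpath <- tempfile(fileext = ".yaml")
  write_missingness(mspec, mpath)
  mspec2 <- read_missingness(mpath)
  expect_identical(induce_missingness(co, mspec2),
                   induce_missingness(co, mspec))
})
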
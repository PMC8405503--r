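test_that("individual predictions scale as expected with the random effects", {
  m <- ft4_model()
  m$wref <- 6
  wfun <- function(t) 3.3 + 0.012 * t
  tt <- c(0, 15, 60, 200)
  p0 <- individual_prediction(m, c(0, 0, 0), 0, 25, wfun, tt)
  expect_true(all(p0 > 0))
  # typical-subject prediction equals the structural simulation
  pk <- pk_parameters(wref = 6)
  prof <- simulate_ft4_profile(pk, expand_regimen(0, 25, 200), wfun, tt)
  expect_equal(p0, prof$ft4, tolerance = 1e-12)
  # doubling kendo doubles the no-dose baseline
  pb <- individual_prediction(m, c(log(2), 0, 0), numeric(0), numeric(0),
                              wfun, 0)
  expect_equal(pb, 2 * individual_prediction(m, c(0, 0, 0), numeric(0),
                                             numeric(0), wfun, 0))
  expect_true(all(individual_prediction(m, c(1, -0.5, 0.3), 0, 25, wfun,
                                        tt) > 0))
})

test_that("with no IIV the -2LL equals the closed-form proportional-error sum", {
  d <- tiny_dataset()
  m <- ft4_model(omega = c(kendo = 0, fV = 0, betaW = 0), sigma_prop = 0.2)
  m2 <- minus2ll(m, d, response = "ft4")
  mm <- m
  mm$wref <- stats::median(d$observations$weight)
  wfun <- interpolate_trajectory(d$observations$t, d$observations$weight)
  cpred <- individual_prediction(mm, c(0, 0, 0), d$observations$t,
                                 d$observations$dose_daily, wfun,
                                 d$observations$t)
  closed <- -2 * sum(stats::dnorm(d$observations$ft4, cpred, 0.2 * cpred,
                                  log = TRUE))
  expect_equal(m2, closed, tolerance = 1e-8)
})

test_that("a single exact observation gives the textbook zero-residual -2LL", {
  m <- ft4_model(omega = c(kendo = 0, fV = 0, betaW = 0), sigma_prop = 0.15)
  m$wref <- 5
  cpred <- individual_prediction(m, c(0, 0, 0), numeric(0), numeric(0),
                                 5, 0)
  d <- ft4_dataset(
    subjects = data.frame(subject_id = "A", sex = "f", ga_weeks = 40,
                          pna_start_days = 7, severity = "unknown"),
    observations = data.frame(subject_id = "A", t = 0, ft4 = cpred,
                              ft4_ref_low = NA, ft4_ref_up = NA, tsh = NA,
                              weight = 5, dose_daily = NA))
  expect_equal(minus2ll(m, d, response = "ft4"),
               2 * log(0.15 * cpred) + log(2 * pi), tolerance = 1e-10)
})

test_that("the quadrature likelihood agrees with Monte-Carlo marginalization", {
  coh <- likelihood_validation_cohort()
  m <- coh$truth$model
  agq <- minus2ll(m, coh$data)
  mc <- mc_minus2ll(m, coh$data, ndraw = 2e4, seed = 3)
  expect_equal(agq, mc, tolerance = 0.3 / agq)  # desk-scale screen
  # laplace is close to agq on this instance too
  expect_equal(minus2ll(m, coh$data, method = "laplace"), agq,
               tolerance = 0.2 / agq)
})

test_that("near-noiseless fixed effects are recovered within 1%", {
  truth <- ft4_model(omega = c(kendo = 0, fV = 0, betaW = 0),
                     sigma_prop = 0.005)
  coh <- generate_cohort(small_cohort_config(10, model = truth), seed = 21)
  start <- ft4_model(kendo = 3, fV = 4, betaW = 0.6,
                     omega = c(kendo = 0, fV = 0, betaW = 0),
                     sigma_prop = 0.01)
  fit <- fit_ft4(coh$data, start = start,
                 estimate = c("kendo", "fV", "betaW", "sigma_prop"),
                 se = FALSE)
  est <- coef(fit)
  expect_equal(est[["kendo"]], 3.66, tolerance = 0.01)
  expect_equal(est[["fV"]], 4.96, tolerance = 0.01)
  expect_equal(est[["betaW"]], 0.753, tolerance = 0.01)
})

test_that("fitting is deterministic: identical inputs replay bit-identically", {
  coh <- generate_cohort(small_cohort_config(8), seed = 31)
  f1 <- fit_ft4(coh$data, start = ft4_model(), se = FALSE,
                control = list(rel.tol = 1e-6))
  f2 <- fit_ft4(coh$data, start = ft4_model(), se = FALSE,
                control = list(rel.tol = 1e-6))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$minus2ll, f2$minus2ll)
  expect_identical(f1$eta, f2$eta)
})

test_that("empirical Bayes estimates shrink and satisfy the shrinkage identity", {
  fit <- cached_small_fit()
  ebe <- empirical_bayes(fit)
  expect_equal(nrow(ebe), fit$n_subjects)
  # the EBEs are no more dispersed than the estimated population sd
  # (up to a small finite-sample wobble that can make shrinkage dip
  # slightly negative)
  expect_lte(stats::sd(ebe$eta_kendo), 1.05 * coef(fit)[["omega_kendo"]])
  sh <- attr(ebe, "shrinkage_pct")
  expect_equal(sh[["kendo"]],
               (1 - stats::sd(ebe$eta_kendo) / coef(fit)[["omega_kendo"]]) *
                 100, tolerance = 1e-8)
  # a subject with one observation shrinks harder than the data pull
  d <- tiny_dataset()
  d$observations <- d$observations[1, ]
  m <- fit$model
  fit1 <- fit_ft4(d, start = m, estimate = "kendo", se = FALSE,
                  control = list(iter.max = 5, eval.max = 10))
  expect_lt(abs(fit1$eta[1, 1]), 3 * m$omega[["kendo"]])
})

test_that("summary, coef, logLik, predict and residuals methods are coherent", {
  fit <- cached_small_fit()
  expect_output(print(fit), "population model fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.ft4_fit")
  expect_output(print(s), "-2LL")
  expect_equal(as.numeric(logLik(fit)), -fit$minus2ll / 2)
  pr <- predict(fit)
  expect_equal(nrow(pr), fit$n_obs)
  expect_true(all(pr$pred > 0))
  pop <- predict(fit, type = "population")
  expect_false(identical(pr$pred, pop$pred))
  r <- residuals(fit)
  expect_equal(length(r), fit$n_obs)
  expect_equal(residuals(fit, type = "raw"),
               pr$observed - pr$pred, tolerance = 1e-12)
})

test_that("identical nested fits give a null likelihood-ratio result", {
  fit <- cached_small_fit()
  res <- compare_models(fit, fit, df = 1)
  expect_equal(res$delta_ofv, 0)
  expect_false(res$significant)
  expect_false(res$artifact)
  expect_error(compare_models(fit, fit), "more free parameters")
})

test_that("feedback coefficients concentrate near zero on feedback-free data", {
  coh <- generate_cohort(small_cohort_config(15), seed = 77)
  red <- fit_ft4(coh$data, start = ft4_model(), se = FALSE,
                 control = list(rel.tol = 1e-6))
  fs <- red$model
  fs$feedback <- tsh_feedback("additive", "identity", betas = 0)
  full <- fit_ft4(coh$data, start = fs,
                  estimate = c("kendo", "fV", "betaW", "omega_kendo",
                               "omega_fV", "omega_betaW", "sigma_prop",
                               "feedback"),
                  se = FALSE, control = list(rel.tol = 1e-6))
  # the TSH coefficient is tiny relative to the production scale
  expect_lt(abs(coef(full)[["fb_beta1"]]) * 267, 2 * coef(full)[["kendo"]])
  cmp <- compare_models(red, full)
  expect_gte(cmp$delta_ofv, -0.01)
})
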
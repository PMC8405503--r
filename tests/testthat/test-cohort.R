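test_that("the default cohort reproduces the study structure", {
  coh <- generate_cohort(cohort_config(), seed = 42)
  d <- coh$data
  expect_equal(nrow(d$subjects), 61L)
  sev <- table(factor(d$subjects$severity,
                      levels = c("severe", "moderate", "mild", "unknown")))
  expect_equal(as.integer(sev), c(18L, 17L, 21L, 5L))
  visits <- table(d$observations$subject_id)
  expect_true(all(visits >= 4 & visits <= 14))
  # subjects with unknown severity have no baseline FT4 measurement
  base <- d$observations[d$observations$t == 0, ]
  unk <- d$subjects$subject_id[d$subjects$severity == "unknown"]
  expect_true(all(is.na(base$ft4[match(unk, base$subject_id)])))
  expect_equal(sum(is.na(base$ft4)), 5L)
})

test_that("generation is bit-reproducible under a seed and varies across seeds", {
  a <- generate_cohort(cohort_config(), seed = 3)
  b <- generate_cohort(cohort_config(), seed = 3)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$eta, b$truth$eta)
  c3 <- generate_cohort(cohort_config(), seed = 4)
  expect_false(identical(a$truth$eta, c3$truth$eta))
})

test_that("severity strata order the production-rate random effects", {
  coh <- generate_cohort(cohort_config(), seed = 10)
  eta <- coh$truth$eta[, "kendo"]
  sev <- coh$truth$severity
  expect_lt(max(eta[sev == "severe"]), min(eta[sev == "mild"]))
  expect_lt(max(eta[sev == "severe"]), min(eta[sev == "moderate"]))
  expect_lt(max(eta[sev == "moderate"]), min(eta[sev == "mild"]))
})

test_that("stratified kendo sampling follows the ceiling-truncated log-normal law", {
  # pool etas over several cohorts; the marginal must match N(0, omega^2)
  # truncated at the 97th-percentile physiological ceiling, whose moments
  # follow from the standard truncated-normal formulas (independent oracle)
  etas <- unlist(lapply(1:8, function(s)
    generate_cohort(cohort_config(), seed = 200 + s)$truth$eta[, "kendo"]))
  n <- length(etas)
  a <- stats::qnorm(0.97)
  r <- stats::dnorm(a) / stats::pnorm(a)
  exp_mean <- -1.12 * r
  exp_sd <- 1.12 * sqrt(1 - a * r - r^2)
  expect_true(all(etas < 1.12 * a + 1e-9))
  expect_lt(abs(mean(etas) - exp_mean), 3 * exp_sd / sqrt(n))
  expect_lt(abs(stats::sd(etas) - exp_sd), 0.08)
})

test_that("weight trajectories anchor at birth weight and grow monotonically", {
  supp <- generate_weight_trajectory(3.3, 600, seed = 1)
  expect_equal(supp$weight[supp$t == 0], 3.3)
  expect_true(all(diff(supp$weight) > 0))
  f <- attr(supp, "fun")
  expect_equal(f(0), 3.3)
  # cohort median at day 600 within the reported last-follow-up IQR
  coh <- generate_cohort(cohort_config(), seed = 42)
  ob <- coh$data$observations
  med600 <- stats::median(vapply(unique(ob$subject_id), function(s) {
    w <- ob[ob$subject_id == s & !is.na(ob$weight), ]
    interpolate_trajectory(w$t, w$weight)(600)
  }, numeric(1)))
  expect_gte(med600, 9.4)
  expect_lte(med600, 12.7)
})

test_that("TSH courses start high by severity and normalize under treatment", {
  tt <- c(0, 30, 200, 600)
  sev_med <- vapply(1:40, function(s)
    generate_tsh_trajectory("severe", tt, seed = s)$tsh[1], numeric(1))
  mild_med <- vapply(1:40, function(s)
    generate_tsh_trajectory("mild", tt, seed = 1000 + s)$tsh[1], numeric(1))
  expect_gt(stats::median(sev_med), stats::median(mild_med))
  coh <- generate_cohort(cohort_config(), seed = 42)
  ob <- coh$data$observations
  expect_true(all(ob$tsh >= 0.005))
  last_tsh <- vapply(unique(ob$subject_id), function(s) {
    r <- ob[ob$subject_id == s, ]
    r$tsh[which.max(r$t)]
  }, numeric(1))
  expect_gte(stats::median(last_tsh), 0.90)
  expect_lte(stats::median(last_tsh), 4.7)
})

test_that("the assay pool has the requested size, structure and anomalies", {
  pool <- generate_assay_pool(34, 4, seed = 2)
  expect_equal(nrow(pool), 34L)
  expect_true(all(pool$low < pool$up))
  expect_equal(length(unique(paste(pool$low, pool$up))), 34L)
  expect_setequal(unique(pool$center), 1:4)
  # ~10% inflated upper limits, preferentially in the 0-1 month bracket
  up_t <- target_reference_table()$p97_5[pool$bracket]
  n_anom <- sum(pool$up > 1.5 * up_t)
  expect_gte(n_anom, 2)
  expect_lte(n_anom, 6)
  # zero jitter reproduces the target ranges exactly
  pool0 <- generate_assay_pool(34, 4, seed = 2, jitter_sd = 0,
                               anomaly_frac = 0)
  tab <- target_reference_table()
  expect_equal(pool0$low, tab$p2_5[pool0$bracket])
  expect_equal(pool0$up, tab$p97_5[pool0$bracket])
})

test_that("noiseless degenerate cohorts give identical per-class profiles", {
  cfg <- cohort_config(
    n_subjects = 4,
    severity_counts = c(severe = 0, moderate = 4, mild = 0, unknown = 0),
    identity_ranges = TRUE, birth_weight_sdlog = 0, horizon_sdlog = 0,
    start_dose_per_kg = c(12, 12), visits_min = 6, visits_max = 6,
    model = ft4_model(omega = c(kendo = 0, fV = 0, betaW = 0),
                      sigma_prop = 1e-9))
  coh <- generate_cohort(cfg, seed = 5)
  ob <- coh$data$observations
  # same class, same weight, no noise: identical baseline measurements
  base <- ob$ft4[ob$t == 0]
  expect_equal(diff(range(base)), 0, tolerance = 1e-6)
})

test_that("baseline FT4 is right-skewed and the transition to normality happens", {
  coh <- generate_cohort(cohort_config(), seed = 42)
  ob <- coh$data$observations
  base <- ob$ft4[ob$t == 0]
  expect_gt(sample_skewness(base), 0.5)
  last <- vapply(unique(ob$subject_id), function(s) {
    r <- ob[ob$subject_id == s & !is.na(ob$ft4), ]
    r$ft4[which.max(r$t)]
  }, numeric(1))
  expect_lt(sample_skewness(last), sample_skewness(base))
  # last-visit values pass a normality screen in most seeds
  pvals <- vapply(1:5, function(s) {
    obs <- generate_cohort(cohort_config(), seed = 300 + s)$data$observations
    lv <- vapply(unique(obs$subject_id), function(id) {
      r <- obs[obs$subject_id == id & !is.na(obs$ft4), ]
      r$ft4[which.max(r$t)]
    }, numeric(1))
    stats::shapiro.test(lv)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.8)
})
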
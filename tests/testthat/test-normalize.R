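test_that("target-range lookup returns the published percentile pairs", {
  expect_equal(unlist(lookup_target_range(15)[c("r_low_std", "r_up_std")]),
               c(r_low_std = 8.50, r_up_std = 30.50))
  expect_equal(unlist(lookup_target_range(200)[c("r_low_std", "r_up_std")]),
               c(r_low_std = 9.17, r_up_std = 25.28))
  expect_equal(unlist(lookup_target_range(400)[c("r_low_std", "r_up_std")]),
               c(r_low_std = 10.45, r_up_std = 22.35))
})

test_that("age brackets partition 0..1826 days totally and uniquely", {
  days <- 0:1826
  res <- lookup_target_range(days)
  expect_false(anyNA(res$r_up_std))
  # half-open-above convention at the bracket boundaries
  expect_equal(res$r_up_std[days == 30], 30.50)
  expect_equal(res$r_up_std[days == 31], 25.28)
  expect_equal(res$r_up_std[days == 365], 25.28)
  expect_equal(res$r_up_std[days == 366], 22.35)
  expect_error(lookup_target_range(1827), "outside table coverage")
  expect_error(lookup_target_range(-1), "outside table coverage")
})

test_that("scale normalization is the upper-limit ratio rescaling", {
  expect_equal(scale_normalize(10, 20, 30.5), 15.25)
  expect_equal(scale_normalize(7.3, 18, 18), 7.3)   # identity when equal
  expect_equal(scale_normalize(0, 20, 30.5), 0)
  expect_error(scale_normalize(10, 0, 30.5), "positive")
})

test_that("location-scale normalization maps range ends to range ends and can go negative", {
  expect_equal(location_scale_normalize(10, 10, 30, 8.5, 30.5), 8.5)
  expect_equal(location_scale_normalize(30, 10, 30, 8.5, 30.5), 30.5)
  # regression-pinned negative output for a value far below the assay range
  expect_equal(location_scale_normalize(2, 10, 30, 8.5, 30.5), -0.3)
  expect_error(location_scale_normalize(5, 10, 10, 8.5, 30.5), "degenerate")
})

test_that("blended normalization reduces to its parts at t = 0 and t >= ts", {
  x <- 11; rl <- 9; ru <- 29; sl <- 8.5; su <- 30.5
  expect_identical(blended_normalize(x, rl, ru, sl, su, t = 0),
                   scale_normalize(x, ru, su))
  for (t in c(150, 151, 400))
    expect_identical(blended_normalize(x, rl, ru, sl, su, t = t),
                     location_scale_normalize(x, rl, ru, sl, su))
})

test_that("blended normalization matches an independent midpoint evaluation", {
  # oracle: evaluate both formulas separately, then average
  ls <- (10 - 9) * (30.5 - 8.5) / (29 - 9) + 8.5
  sc <- 10 * 30.5 / 29
  expect_equal(blended_normalize(10, 9, 29, 8.5, 30.5, t = 75),
               0.5 * ls + 0.5 * sc, tolerance = 1e-12)
  expect_equal(blended_normalize(10, 9, 29, 8.5, 30.5, t = 75), 10.0586,
               tolerance = 1e-4)
})

test_that("blending is continuous and piecewise-linear in time", {
  args <- list(x_meas = 4, r_low = 10, r_up = 35, r_low_std = 8.5,
               r_up_std = 30.5)
  f <- function(t) do.call(blended_normalize, c(args, list(t = t)))
  expect_equal(f(150 - 1e-9), f(150), tolerance = 1e-7)
  tt <- seq(0, 150, by = 10)
  vals <- vapply(tt, f, numeric(1))
  expect_equal(max(abs(diff(diff(vals)))), 0, tolerance = 1e-10)
})

test_that("all three normalizers are increasing in the measurement and fix identical ranges", {
  set.seed(42)
  for (rep in 1:20) {
    rl <- runif(1, 5, 12); ru <- rl + runif(1, 5, 30)
    sl <- runif(1, 8, 11); su <- sl + runif(1, 10, 25)
    t <- runif(1, 0, 300)
    x <- sort(runif(2, 0, 40))
    expect_lt(scale_normalize(x[1], ru, su), scale_normalize(x[2], ru, su))
    expect_lt(location_scale_normalize(x[1], rl, ru, sl, su),
              location_scale_normalize(x[2], rl, ru, sl, su))
    expect_lt(blended_normalize(x[1], rl, ru, sl, su, t),
              blended_normalize(x[2], rl, ru, sl, su, t))
    # fixed point when the assay range equals the target range
    expect_equal(blended_normalize(x[1], sl, su, sl, su, t), x[1],
                 tolerance = 1e-12)
    expect_gte(scale_normalize(x[1], ru, su), 0)
  }
})

test_that("dataset normalization uses measurement-time PNA and flags rangeless rows", {
  d <- tiny_dataset()
  # second visit at t = 30 with pna_start 7 -> PNA 37 -> 1-12 month bracket
  dn <- normalize_ft4(d)
  ob <- dn$observations
  expect_equal(ob$ft4_norm[1],
               blended_normalize(6, 8.5, 30.5, 8.50, 30.50, t = 0))
  expect_equal(ob$ft4_norm[2],
               blended_normalize(22, 8.5, 30.5, 9.17, 25.28, t = 30))
  d$observations$ft4_ref_up[2] <- NA
  expect_warning(dn2 <- normalize_ft4(d), "not normalized")
  expect_true(is.na(dn2$observations$ft4_norm[2]))
  expect_true(dn2$observations$ft4_norm_skipped[2])
  expect_equal(attr(dn2, "n_skipped"), 1L)
})

test_that("identity assay ranges give an identity normalization dataset-wide", {
  coh <- generate_cohort(small_cohort_config(10), seed = 8)
  dn <- normalize_ft4(coh$data)
  ob <- dn$observations
  i <- !is.na(ob$ft4)
  expect_equal(ob$ft4_norm[i], ob$ft4[i], tolerance = 1e-12)
})

test_that("normalized values for t beyond the blend threshold are never negative on generated cohorts", {
  coh <- generate_cohort(cohort_config(), seed = 6)
  dn <- suppressWarnings(normalize_ft4(coh$data))
  ob <- dn$observations
  late <- ob$t > 150 & !is.na(ob$ft4_norm)
  expect_true(all(ob$ft4_norm[late] > 0))
  # row-wise re-evaluation oracle
  su <- dn$subjects
  pna <- su$pna_start_days[match(ob$subject_id, su$subject_id)] + ob$t
  i <- which(!is.na(ob$ft4_norm))
  std <- lookup_target_range(pmin(pna[i], 1826))
  again <- blended_normalize(ob$ft4[i], ob$ft4_ref_low[i], ob$ft4_ref_up[i],
                             std$r_low_std, std$r_up_std, t = ob$t[i])
  expect_equal(ob$ft4_norm[i], again, tolerance = 1e-12)
})

test_that("severity classification follows the guideline thresholds", {
  expect_equal(classify_severity(c(4.9, 5.0, 9.99, 10.0, NA)),
               c("severe", "moderate", "moderate", "mild", "unknown"))
  expect_error(classify_severity(-1), "non-negative")
})

test_that("window summaries compare raw and normalized medians", {
  d <- tiny_dataset()
  dn <- normalize_ft4(d)
  tab <- summarize_comparison(dn, windows = list(all = c(0, 100)))
  expect_equal(tab$n, 2L)
  expect_equal(tab$median_raw, 14)
  # single-value window: degenerate IQR, no test
  tab1 <- summarize_comparison(dn, windows = list(one = c(0, 0)))
  expect_equal(tab1$median_raw, 6)
  expect_equal(tab1$q25_raw, tab1$q75_raw)
  # identity normalization: identical medians, no significance
  coh <- generate_cohort(small_cohort_config(10), seed = 8)
  dni <- normalize_ft4(coh$data)
  ti <- summarize_comparison(dni)
  expect_equal(ti$median_raw, ti$median_norm)
  # empty window yields absent statistics, not an error
  te <- summarize_comparison(dn, windows = list(none = c(900, 901)))
  expect_equal(te$n, 0L)
  expect_true(is.na(te$median_raw))
})

test_that("normalization lowers the medians when assay upper limits run high", {
  coh <- generate_cohort(cohort_config(), seed = 9)
  dn <- suppressWarnings(normalize_ft4(coh$data))
  tab <- summarize_comparison(dn)
  lower <- tab$median_norm <= tab$median_raw
  expect_gte(sum(lower), 3)
})

test_that("skewness diagnostics see the right-skew-to-normal transition", {
  set.seed(33)
  expect_lt(abs(sample_skewness(rnorm(4000))), 0.15)
  expect_gt(sample_skewness(rexp(4000)), 1)
  coh <- generate_cohort(cohort_config(), seed = 4)
  dn <- suppressWarnings(normalize_ft4(coh$data))
  sk <- skewness_diagnostic(dn)
  expect_gt(sk$skewness[sk$window == "t = 0"],
            sk$skewness[sk$window == "last visit"])
  # undersized windows give absent statistics
  d <- tiny_dataset()
  sk1 <- skewness_diagnostic(normalize_ft4(d),
                             windows = list(one = c(0, 0)))
  expect_true(is.na(sk1$skewness))
})
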
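test_that("dose conversion uses the fixed 1.29 factor", {
  expect_equal(convert_dose_mcg_to_nmol(25), 32.25)
  expect_equal(convert_dose_mcg_to_nmol(0), 0)
  expect_equal(convert_dose_mcg_to_nmol(50), 64.5)
  expect_error(convert_dose_mcg_to_nmol(-1), "non-negative")
})

test_that("volume of distribution follows the allometric power law", {
  p <- pk_parameters()
  expect_equal(volume_of_distribution(p$wref, p), p$fV)
  expect_equal(volume_of_distribution(2 * p$wref, p), 4.96 * 2^0.753,
               tolerance = 1e-12)
  expect_equal(volume_of_distribution(2 * p$wref, p), 8.36, tolerance = 1e-3)
  p0 <- pk_parameters(betaW = 0)
  expect_equal(volume_of_distribution(c(2, 5, 11), p0), rep(4.96, 3))
  expect_error(volume_of_distribution(0, p), "positive")
})

test_that("the equilibrium amount is kendo/kel and is reached without dosing", {
  p <- pk_parameters()
  expect_equal(baseline_amount(p), 36.6)
  expect_equal(baseline_amount(pk_parameters(kendo = 0)), 0)
  # long-horizon numeric integration oracle with no doses
  no_dose <- data.frame(t = numeric(0), dose = numeric(0))
  sol <- simulate_amounts_numeric(p, no_dose, c(0, 500, 1000))
  expect_equal(sol$A_C, rep(36.6, 3), tolerance = 1e-7)
  an <- simulate_amounts(p, no_dose, c(0, 250, 800))
  expect_equal(an$A_C, rep(36.6, 3))
  expect_equal(an$A_B, rep(0, 3))
})

test_that("FT4 concentration is the free fraction over the volume", {
  p <- pk_parameters()
  expect_equal(ft4_concentration(36.6, p$wref, p), 0.3 * 36.6 / 4.96,
               tolerance = 1e-12)
  expect_equal(ft4_concentration(36.6, p$wref, p), 2.2137, tolerance = 1e-4)
  expect_equal(ft4_concentration(0, 5, p), 0)
  p2 <- pk_parameters(fV = 2 * 4.96)
  expect_equal(ft4_concentration(36.6, p$wref, p2),
               ft4_concentration(36.6, p$wref, p) / 2)
  # the constant 0.3 is 0.03% of T4 times the nmol->pmol factor
  expect_equal(0.03 / 100 * 1000, 0.3)
})

test_that("regimen expansion carries doses forward day by day", {
  reg <- expand_regimen(c(0, 10), c(25, 37.5), 14)
  expect_equal(nrow(reg), 15)
  expect_equal(reg$dose[reg$t < 10], rep(25, 10))
  expect_equal(reg$dose[reg$t >= 10], rep(37.5, 5))
  expect_error(expand_regimen(c(5, 5), c(10, 10), 8), "strictly increasing")
  expect_error(expand_regimen(0, -5, 8), "positive")
  expect_equal(nrow(expand_regimen(numeric(0), numeric(0), 10)), 0)
})

test_that("after stopping treatment the system returns to equilibrium at rate kel", {
  p <- pk_parameters()
  single <- data.frame(t = 0, dose = 50)
  tt <- c(30, 40, 50)
  sol <- simulate_amounts(p, single, tt)
  dev <- sol$A_C - baseline_amount(p)
  expect_true(all(dev > 0))
  # log-linear decay at rate kel (absorption long finished)
  rates <- -diff(log(dev)) / diff(tt)
  expect_equal(rates, rep(p$kel, 2), tolerance = 1e-4)
  # half-life ~ 7 days
  expect_equal(round(log(2) / p$kel), 7)
})

test_that("a single bolus peaks in the central compartment at the analytic peak time", {
  p <- pk_parameters()
  tmax <- log(p$ka / p$kel) / (p$ka - p$kel)   # about 0.266 day
  grid <- seq(0.01, 2, by = 0.001)
  sol <- simulate_amounts(p, data.frame(t = 0, dose = 25), grid)
  expect_equal(grid[which.max(sol$A_C)], tmax, tolerance = 2e-3)
  expect_equal(tmax, 0.2663, tolerance = 1e-3)
  # absorption compartment decays monotonically after the bolus
  expect_true(all(diff(sol$A_B) < 0))
})

test_that("the analytic solver matches the ODE integrator on random regimens", {
  set.seed(7)
  for (rep in 1:5) {
    p <- pk_parameters(kendo = runif(1, 0.5, 8), fV = runif(1, 2, 8),
                       betaW = runif(1, 0.3, 1.2), ka = runif(1, 5, 30),
                       kel = runif(1, 0.05, 0.3))
    n_seg <- sample(1:4, 1)
    t_seg <- sort(sample(0:50, n_seg)); t_seg[1] <- 0
    reg <- expand_regimen(t_seg, runif(n_seg, 12.5, 75), 60)
    tt <- sort(runif(6, 0.1, 60.5))
    an <- simulate_amounts(p, reg, tt)
    nu <- simulate_amounts_numeric(p, reg, tt)
    expect_equal(an$A_C, nu$A_C, tolerance = 1e-6)
    big <- nu$A_B > 1e-6 * max(nu$A_B)
    expect_equal(an$A_B[big], nu$A_B[big], tolerance = 1e-6)
  }
})

test_that("the equal-rate degenerate case uses the analytic limit", {
  p_eq <- pk_parameters(ka = 0.1, kel = 0.1)
  reg <- data.frame(t = 0, dose = 25)
  tt <- c(0.5, 2, 5, 20)
  an <- simulate_amounts(p_eq, reg, tt)
  nu <- simulate_amounts_numeric(p_eq, reg, tt)
  expect_equal(an$A_C, nu$A_C, tolerance = 1e-6)
  # continuity in ka near the degeneracy
  p_near <- pk_parameters(ka = 0.1 + 1e-12, kel = 0.1)
  an2 <- simulate_amounts(p_near, reg, tt)
  expect_equal(an$A_C, an2$A_C, tolerance = 1e-6)
})

test_that("the system is linear: dose superposition adds responses", {
  p <- pk_parameters()
  r1 <- data.frame(t = c(0, 1, 2), dose = rep(25, 3))
  r2 <- data.frame(t = c(0.5, 1.5), dose = rep(50, 2))
  tt <- c(0.7, 2.2, 5, 12)
  base <- baseline_amount(p)
  both <- simulate_amounts(p, rbind(r1, r2)[order(c(r1$t, r2$t)), ], tt)
  a1 <- simulate_amounts(p, r1, tt)
  a2 <- simulate_amounts(p, r2, tt)
  expect_equal(both$A_C, a1$A_C + a2$A_C - base, tolerance = 1e-12)
})

test_that("FT4 profiles respond to weight only through the volume", {
  p <- pk_parameters()
  # no doses, constant weight: flat profile at the endogenous equilibrium
  flat <- simulate_ft4_profile(p, NULL, p$wref, c(0, 10, 100))
  expect_equal(flat$ft4, rep(0.3 * 36.6 / 4.96, 3))
  # no doses, growing weight: strictly decreasing FT4
  wfun <- function(t) 3.3 + 0.015 * t
  dec <- simulate_ft4_profile(p, NULL, wfun, seq(0, 400, by = 50))
  expect_true(all(diff(dec$ft4) < 0))
})

test_that("daily dosing settles at the closed-form average steady state", {
  p <- pk_parameters()
  reg <- expand_regimen(0, 25, 300)
  tt <- seq(299, 300, by = 0.001)
  prof <- simulate_ft4_profile(p, reg, p$wref, tt)
  target <- 0.3 * (3.66 + 0.6 * 1.29 * 25) / (0.1 * 4.96)   # 13.92
  expect_equal(mean(prof$ft4), target, tolerance = 1e-3)
  expect_equal(target, 13.92, tolerance = 1e-3)
})

test_that("amounts and concentrations stay non-negative on random inputs", {
  set.seed(11)
  for (rep in 1:10) {
    p <- pk_parameters(kendo = runif(1, 0, 5), ka = runif(1, 1, 25),
                       kel = runif(1, 0.05, 0.5))
    reg <- expand_regimen(0, runif(1, 12.5, 75), 30)
    sol <- simulate_amounts(p, reg, sort(runif(8, 0, 40)))
    expect_true(all(sol$A_B >= 0) && all(sol$A_C >= 0))
  }
})
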
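# Shared fixtures and independent oracles used across the test files.

# A tiny hand-built dataset: one subject, two visits.
tiny_dataset <- function() {
  ft4_dataset(
    subjects = data.frame(subject_id = "A", sex = "f", ga_weeks = 40,
                          pna_start_days = 7, severity = "moderate"),
    observations = data.frame(
      subject_id = "A", t = c(0, 30), ft4 = c(6, 22),
      ft4_ref_low = c(8.5, 8.5), ft4_ref_up = c(30.5, 30.5),
      tsh = c(250, 5), weight = c(3.3, 4.4), dose_daily = c(25, 25)))
}

# Monte-Carlo marginalization of the -2 log-likelihood by plain prior
# sampling: an oracle for the quadrature-based likelihood that shares none
# of the Laplace/AGQ machinery.  The structural prediction is assembled
# directly from the model equations (dose superposition from the analytic
# solver, which is itself cross-checked against the ODE integrator
# elsewhere).
mc_minus2ll <- function(model, data, ndraw = 1e5, seed = 1) {
  set.seed(seed)
  ob <- data$observations
  if (is.null(model$wref)) model$wref <- stats::median(ob$weight, na.rm = TRUE)
  total <- 0
  for (id in unique(ob$subject_id)) {
    rows <- ob[ob$subject_id == id, ]
    use <- !is.na(rows$ft4)
    tt <- rows$t[use]; y <- rows$ft4[use]
    wr <- rows[!is.na(rows$weight), ]
    W <- interpolate_trajectory(wr$t, wr$weight)(tt)
    dr <- rows[!is.na(rows$dose_daily), ]
    reg <- expand_regimen(dr$t, dr$dose_daily, max(tt))
    p0 <- pk_parameters(kendo = 0, fV = model$fV, betaW = model$betaW,
                        ka = model$ka, kel = model$kel, F = model$F,
                        wref = model$wref)
    S <- simulate_amounts(p0, reg, tt)$A_C
    wr_ratio <- W / model$wref
    e1 <- stats::rnorm(ndraw, 0, model$omega["kendo"])
    e2 <- stats::rnorm(ndraw, 0, model$omega["fV"])
    e3 <- stats::rnorm(ndraw, 0, model$omega["betaW"])
    ll <- numeric(ndraw)
    for (k in seq_len(ndraw)) {
      cpred <- 0.3 * (model$kendo * exp(e1[k]) / model$kel + S) /
        (model$fV * exp(e2[k]) * wr_ratio^(model$betaW * exp(e3[k])))
      ll[k] <- sum(stats::dnorm(y, cpred, model$sigma_prop * cpred,
                                log = TRUE))
    }
    mx <- max(ll)
    total <- total - 2 * (mx + log(mean(exp(ll - mx))))
  }
  total
}

# The 3-subject instance used to validate the likelihood approximation:
# moderate variability so that plain prior sampling has good overlap with
# each subject's conditional density.
likelihood_validation_cohort <- function() {
  generate_cohort(cohort_config(
    identity_ranges = TRUE, n_subjects = 3,
    severity_counts = c(severe = 1, moderate = 1, mild = 1, unknown = 0),
    visits_min = 4, visits_max = 5, visits_mean = 4,
    model = ft4_model(omega = c(kendo = 0.3, fV = 0.2, betaW = 0.2),
                      sigma_prop = 0.3)), seed = 5)
}

# A reduced cohort configuration shared by the estimation and diagnostics
# tests (and the TSH-feedback power study at n = 30).
small_cohort_config <- function(n = 25, model = ft4_model(),
                                identity_ranges = TRUE, ...) {
  counts <- c(severe = round(0.3 * n), moderate = round(0.28 * n),
              mild = n - round(0.3 * n) - round(0.28 * n) - round(0.08 * n),
              unknown = round(0.08 * n))
  cohort_config(n_subjects = n, severity_counts = counts,
                identity_ranges = identity_ranges, model = model, ...)
}

# One moderately sized fit, computed once per test run and reused.
cached_small_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      coh <- generate_cohort(small_cohort_config(25), seed = 101)
      val <<- fit_ft4(coh$data, start = ft4_model(), se = FALSE,
                      control = list(rel.tol = 1e-7))
      attr(val, "truth") <<- coh$truth
    }
    val
  }
})
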
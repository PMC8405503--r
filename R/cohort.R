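#' Configuration for the synthetic multi-center cohort generator
#'
#' Captures the statistical structure of a retrospective multi-center cohort
#' of newborns and infants with congenital hypothyroidism treated with
#' levothyroxine: 61 subjects in severity classes severe/moderate/mild
#' 18/17/21 plus 5 with missing baseline FT4; 4 to 14 FT4 visits per subject
#' (mean about 8) over a follow-up of roughly two years; weight-per-kg dosing
#' started at 10-15 mcg/kg/day in tablet steps and titrated at visits when
#' FT4 leaves the target range; infant weight growth from a median 3.3 kg at
#' birth towards a median 11.3 kg around day 600; high baseline TSH
#' (severity-correlated, median a few hundred mU/l) normalizing under
#' treatment; about 34 distinct assay reference ranges spread over 4 centers
#' with a few inflated early upper limits.
#'
#' @param n_subjects number of subjects.
#' @param severity_counts named counts for `severe`, `moderate`, `mild`,
#'   `unknown`; must sum to `n_subjects`.  `unknown` subjects have their
#'   baseline FT4 masked as missing.
#' @param visits_min,visits_max,visits_mean visit-count distribution
#'   (binomial shifted to `[visits_min, visits_max]`).
#' @param horizon_median,horizon_sdlog follow-up length per subject (days,
#'   log-normal, truncated to `horizon_range`).
#' @param horizon_range allowed follow-up range, days.
#' @param start_dose_per_kg range of the initial dose, mcg/kg/day.
#' @param dose_step,dose_min,dose_max tablet granularity and limits, mcg/day.
#' @param birth_weight_median,birth_weight_sdlog birth weight distribution, kg.
#' @param growth_tau mean time constant of the saturating-exponential growth
#'   curve, days.
#' @param n_assay_ranges,n_centers,assay_jitter_sd,assay_anomaly_frac assay
#'   reference-range pool (see [generate_assay_pool()]).
#' @param identity_ranges if `TRUE`, every measurement is tagged with the
#'   target reference range itself (normalization becomes the identity) and
#'   no ranges are missing.
#' @param weight_missing_prob,range_missing_prob missingness switches
#'   exercising the skip/flag paths downstream.
#' @param tsh_baseline_median named per-severity medians of baseline TSH,
#'   mU/l.
#' @param tsh_target_median,tsh_tau TSH level approached under treatment
#'   (mU/l) and the decay time constant (days).
#' @param model the true [ft4_model()] used for generation (`wref = NULL`
#'   means: use the median of the generated weight observations, mirroring
#'   how a fit derives it).
#' @param seed default seed used when [generate_cohort()] is called without
#'   one.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 61,
                          severity_counts = c(severe = 18, moderate = 17,
                                              mild = 21, unknown = 5),
                          visits_min = 4, visits_max = 14, visits_mean = 8,
                          horizon_median = 600, horizon_sdlog = 0.3,
                          horizon_range = c(150, 765),
                          start_dose_per_kg = c(10, 15),
                          dose_step = 12.5, dose_min = 12.5, dose_max = 75,
                          birth_weight_median = 3.3, birth_weight_sdlog = 0.18,
                          growth_tau = 280,
                          n_assay_ranges = 34, n_centers = 4,
                          assay_jitter_sd = 0.12, assay_anomaly_frac = 0.1,
                          identity_ranges = FALSE,
                          weight_missing_prob = 0.06,
                          range_missing_prob = 0.02,
                          tsh_baseline_median = c(severe = 450, moderate = 267,
                                                  mild = 140),
                          tsh_target_median = 2.2, tsh_tau = 45,
                          model = ft4_model(), seed = 1L) {
  stopifnot(sum(severity_counts) == n_subjects,
            visits_min >= 2, visits_max >= visits_min,
            inherits(model, "ft4_model"))
  structure(as.list(environment()), class = "cohort_config")
}

#' Sample a saturating-exponential infant growth curve
#'
#' `W(t) = W_inf - (W_inf - birth_weight) * exp(-t / tau)`: anchored exactly
#' at the birth weight at `t = 0`, monotone increasing, levelling off in the
#' second year.  The population defaults put the median near 3.3 kg at birth
#' and near 11.3 kg at day 600.
#'
#' @param birth_weight kg, > 0.
#' @param horizon follow-up length, days (used for the returned support grid).
#' @param seed integer seed.
#' @param tau growth time constant, days (jittered per subject).
#' @return data.frame of monthly support points `t`, `weight`; the smooth
#'   curve itself is attached as attribute `"fun"`.
#' @export
generate_weight_trajectory <- function(birth_weight, horizon, seed,
                                       tau = 280) {
  stopifnot(birth_weight > 0)
  set.seed(seed)
  # asymptote calibrated so that a median newborn reaches ~11.3 kg at day 600
  w_inf <- 12.36 * (birth_weight / 3.3)^0.3 * exp(stats::rnorm(1, 0, 0.10))
  w_inf <- max(w_inf, birth_weight * 1.5)
  tau_i <- tau * exp(stats::rnorm(1, 0, 0.15))
  fun <- function(t) w_inf - (w_inf - birth_weight) * exp(-t / tau_i)
  supp <- data.frame(t = seq(0, max(horizon, 30), by = 30))
  supp$weight <- fun(supp$t)
  attr(supp, "fun") <- fun
  supp
}

#' Sample a TSH time course for one subject
#'
#' High baseline (heavier for more severe disease), exponential-like
#' normalization of log-TSH towards the treated level, multiplicative noise
#' on the recorded values, floored at the 0.005 mU/l limit of
#' quantification.
#'
#' @param severity `"severe"`, `"moderate"`, `"mild"` or `"unknown"`
#'   (treated as moderate).
#' @param times observation times, days.
#' @param seed integer seed.
#' @param baseline_median named per-severity baseline medians, mU/l.
#' @param target_median treated TSH level, mU/l.
#' @param tau decay time constant of log-TSH, days.
#' @param noise_sdlog multiplicative noise on recorded values.
#' @return data.frame `t`, `tsh` (recorded values); the smooth underlying
#'   curve is attached as attribute `"fun"`.
#' @export
generate_tsh_trajectory <- function(severity, times, seed,
                                    baseline_median = c(severe = 450,
                                                        moderate = 267,
                                                        mild = 140),
                                    target_median = 2.2, tsh_tau = 45,
                                    noise_sdlog = 0.25, tau = tsh_tau) {
  set.seed(seed)
  sev <- if (severity %in% names(baseline_median)) severity else "moderate"
  tsh0 <- baseline_median[[sev]] * exp(stats::rnorm(1, 0, 0.6))
  targ <- target_median * exp(stats::rnorm(1, 0, 0.7))
  ltsh0 <- log(tsh0); ltarg <- log(targ)
  fun <- function(t) pmax(exp(ltarg + (ltsh0 - ltarg) * exp(-t / tau)),
                          .tsh_floor)
  obs <- fun(times) * exp(stats::rnorm(length(times), 0, noise_sdlog))
  data.frame(t = times, tsh = pmax(obs, .tsh_floor)) |>
    structure(fun = fun)
}

#' Generate a pool of assay-specific FT4 reference ranges
#'
#' Draws `n_ranges` reference ranges spread over `n_centers` centers, assay
#' eras and postnatal-age brackets, as multiplicative jitter around the
#' target reference range.  A configurable fraction of the pool — placed
#' preferentially in the 0-1 month bracket — gets an inflated upper limit
#' (1.6 to 2.4 times the target), emulating the unusually large early upper
#' limits seen when adult reference ranges were applied to neonates.
#'
#' @param n_ranges pool size (>= `n_centers`).
#' @param n_centers number of centers.
#' @param seed integer seed.
#' @param jitter_sd log-scale jitter of the limits around the target range.
#' @param anomaly_frac fraction of the pool with inflated upper limits.
#' @param table target reference table.
#' @return data.frame `range_id`, `center`, `era`, `bracket`, `low`, `up`.
#' @export
generate_assay_pool <- function(n_ranges = 34, n_centers = 4, seed = 1L,
                                jitter_sd = 0.12, anomaly_frac = 0.1,
                                table = target_reference_table()) {
  stopifnot(n_ranges >= n_centers)
  set.seed(seed)
  n_brackets <- nrow(table)
  n_eras <- max(1L, ceiling(n_ranges / (n_centers * n_brackets)))
  grid <- expand.grid(center = seq_len(n_centers), era = seq_len(n_eras),
                      bracket = seq_len(n_brackets))
  # era 1 keeps full coverage so every (center, bracket) always resolves
  keep_first <- grid$era == 1L
  extra <- which(!keep_first)
  n_extra <- n_ranges - sum(keep_first)
  if (n_extra < 0) stop("n_ranges too small for full era-1 coverage")
  sel <- c(which(keep_first), sample(extra, min(n_extra, length(extra))))
  pool <- grid[sel, , drop = FALSE]
  # top up with duplicated strata if the grid was too small
  while (nrow(pool) < n_ranges)
    pool <- rbind(pool, grid[sample(nrow(grid), 1), ])
  pool <- pool[seq_len(n_ranges), , drop = FALSE]
  lo_t <- table$p2_5[pool$bracket]
  up_t <- table$p97_5[pool$bracket]
  pool$low <- lo_t * exp(stats::rnorm(n_ranges, 0, jitter_sd))
  pool$up <- up_t * exp(stats::rnorm(n_ranges, 0, jitter_sd))
  n_anom <- round(anomaly_frac * n_ranges)
  if (n_anom > 0) {
    cand <- which(pool$bracket == 1L)
    if (length(cand) < n_anom) cand <- seq_len(n_ranges)
    anom <- sample(cand, n_anom)
    pool$up[anom] <- up_t[anom] * stats::runif(n_anom, 1.6, 2.4)
  }
  pool$low <- pmin(pool$low, 0.8 * pool$up)
  pool$range_id <- seq_len(n_ranges)
  rownames(pool) <- NULL
  pool[, c("range_id", "center", "era", "bracket", "low", "up")]
}

# stratified sampling of eta_kendo: severity strata are the quantile
# partition of N(0, omega^2) so the marginal law is exactly the generative
# one (up to a 97th-percentile ceiling: residual gland function in a CH
# cohort cannot reach euthyroid-level production) while severe subjects get
# the lowest production rates
.sample_eta_kendo <- function(severity, omega, u_cap = 0.97) {
  counts <- table(factor(severity[severity != "unknown"],
                         levels = c("severe", "moderate", "mild")))
  tot <- sum(counts)
  cuts <- c(0, cumsum(counts) / tot)
  eta <- numeric(length(severity))
  for (j in seq_len(3)) {
    lab <- c("severe", "moderate", "mild")[j]
    i <- which(severity == lab)
    if (!length(i)) next
    u <- stats::runif(length(i), cuts[j], min(cuts[j + 1], u_cap))
    eta[i] <- omega * stats::qnorm(u)
  }
  i <- which(severity == "unknown")
  if (length(i))
    eta[i] <- omega *
      stats::qnorm(stats::runif(length(i), 0, u_cap))
  eta
}

.round_dose <- function(d, step, lo, hi) pmin(pmax(round(d / step) * step, lo), hi)

#' Generate a synthetic multi-center congenital-hypothyroidism cohort
#'
#' Simulates a full longitudinal dataset from the structural FT4 model with
#' known ("true") population parameters, ready to be normalized, fitted and
#' compared against the generating values.  Per subject: a severity class, a
#' kendo random effect drawn from its severity stratum (see Details), random
#' effects for `fV` and `betaW`, a growth curve, a TSH course, a visit
#' schedule, a titrated dose regimen (dose stepped up/down by one tablet
#' step when the measured FT4 leaves the target range at a visit), FT4
#' measurements with proportional noise, and an assay reference range from
#' the subject's center/era pool.
#'
#' @details
#' Severity strata for `eta_kendo` are the quantile partition of
#' `N(0, omega_kendo^2)` at the cumulative class fractions, a stratified
#' sampling scheme that preserves the generative log-normal law exactly
#' (required for parameter-recovery experiments) while guaranteeing that
#' severe subjects carry the least residual gland function.  `"unknown"`
#' subjects draw unrestricted and have their baseline FT4 masked.
#'
#' All randomness flows from `seed` through named substreams
#' (structure / weights / assays / TSH / random effects / noise), so a
#' cohort is bit-reproducible from `(config, seed)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list of class `ft4_cohort` with elements `data` (an
#'   [ft4_dataset()]) and `truth` (the generating [ft4_model()] with `wref`
#'   resolved, the per-subject `eta` matrix, severity labels and the seed).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  set.seed(seed)
  sub_seeds <- sample.int(2147483646L, 6)
  n <- cf$n_subjects
  ids <- sprintf("S%02d", seq_len(n))
  m <- cf$model

  ## -- cohort structure: severity, demographics, visit schedules ----------
  set.seed(sub_seeds[1])
  severity <- sample(rep(names(cf$severity_counts), cf$severity_counts))
  pna_start <- pmax(3, round(exp(stats::rnorm(n, log(7), 0.3)) +
                               ifelse(stats::runif(n) < 0.07,
                                      exp(stats::rnorm(n, log(60), 0.8)), 0)))
  pna_start <- pmin(pna_start, 231)
  ga <- round(pmin(pmax(stats::rnorm(n, 39.8, 2.2), 28), 43), 1)
  ga[sample(n, min(13, n))] <- NA
  sex <- sample(c("f", "m"), n, replace = TRUE, prob = c(0.7, 0.3))
  horizon <- round(pmin(pmax(exp(stats::rnorm(n, log(cf$horizon_median),
                                              cf$horizon_sdlog)),
                             cf$horizon_range[1]), cf$horizon_range[2]))
  n_visits <- if (cf$visits_max > cf$visits_min) {
    p_extra <- min(max((cf$visits_mean - cf$visits_min) /
                         (cf$visits_max - cf$visits_min), 0), 1)
    cf$visits_min + stats::rbinom(n, cf$visits_max - cf$visits_min, p_extra)
  } else rep(cf$visits_min, n)
  visit_times <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_visits[i] - 1L
    for (try in 1:50) {
      tt <- sort(round(horizon[i] * stats::runif(k)^1.7))
      tt <- tt[tt >= 7]
      if (length(unique(tt)) == k) break
    }
    visit_times[[i]] <- c(0, unique(tt))
  }

  ## -- weight trajectories ------------------------------------------------
  set.seed(sub_seeds[2])
  wb <- pmin(pmax(cf$birth_weight_median *
                    exp(stats::rnorm(n, 0, cf$birth_weight_sdlog)), 0.95), 8)
  wt_seeds <- sample.int(2147483646L, n)
  wfun <- vector("list", n)
  for (i in seq_len(n)) {
    supp <- generate_weight_trajectory(wb[i], horizon[i], wt_seeds[i],
                                       tau = cf$growth_tau)
    wfun[[i]] <- attr(supp, "fun")
  }

  ## -- assay reference-range pool ----------------------------------------
  set.seed(sub_seeds[3])
  pool_seed <- sample.int(2147483646L, 1)
  pool <- generate_assay_pool(cf$n_assay_ranges, cf$n_centers, pool_seed,
                              jitter_sd = if (cf$identity_ranges) 0 else
                                cf$assay_jitter_sd,
                              anomaly_frac = if (cf$identity_ranges) 0 else
                                cf$assay_anomaly_frac)
  n_eras <- max(pool$era)
  center <- sample(seq_len(cf$n_centers), n, replace = TRUE)
  era <- sample(seq_len(n_eras), n, replace = TRUE)
  table_std <- target_reference_table()

  ## -- TSH courses ---------------------------------------------------------
  set.seed(sub_seeds[4])
  tsh_seeds <- sample.int(2147483646L, n)
  tsh_obs <- vector("list", n)
  tsh_fun <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- generate_tsh_trajectory(severity[i], visit_times[[i]], tsh_seeds[i],
                                  baseline_median = cf$tsh_baseline_median,
                                  target_median = cf$tsh_target_median,
                                  tau = cf$tsh_tau)
    tsh_obs[[i]] <- tr$tsh
    tsh_fun[[i]] <- attr(tr, "fun")
  }

  ## -- random effects ------------------------------------------------------
  set.seed(sub_seeds[5])
  eta <- matrix(0, n, 3, dimnames = list(ids, c("kendo", "fV", "betaW")))
  if (m$omega["kendo"] > 0)
    eta[, 1] <- .sample_eta_kendo(severity, m$omega["kendo"])
  if (m$omega["fV"] > 0) eta[, 2] <- stats::rnorm(n, 0, m$omega["fV"])
  if (m$omega["betaW"] > 0) eta[, 3] <- stats::rnorm(n, 0, m$omega["betaW"])

  ## -- reference weight: median of the weights that will be observed ------
  all_w <- unlist(lapply(seq_len(n),
                         function(i) wfun[[i]](visit_times[[i]])))
  wref <- if (is.null(m$wref)) stats::median(all_w) else m$wref
  m$wref <- wref

  ## -- visit-wise simulation with dose titration ---------------------------
  set.seed(sub_seeds[6])
  obs_list <- vector("list", n)
  for (i in seq_len(n)) {
    tv <- visit_times[[i]]
    p_i <- .individual_params(m, eta[i, ], wref)
    # endogenous contribution (possibly TSH-driven) at arbitrary times
    endo_at <- if (is.null(m$feedback)) {
      function(t) rep(p_i$kendo / p_i$kel, length(t))
    } else {
      days <- seq(0, max(tv), by = 1)
      prod_daily <- kendo_with_feedback(p_i$kendo, tsh_fun[[i]](days),
                                        m$feedback)
      function(t) .endo_response(prod_daily, p_i$kel, t)
    }
    dose_t <- 0
    dose_v <- .round_dose(stats::runif(1, cf$start_dose_per_kg[1],
                                       cf$start_dose_per_kg[2]) * wb[i],
                          cf$dose_step, cf$dose_min, cf$dose_max)
    ft4_meas <- numeric(length(tv))
    rng_low <- rng_up <- numeric(length(tv))
    for (k in seq_along(tv)) {
      t_k <- tv[k]
      regimen <- expand_regimen(dose_t, dose_v, t_k)
      A_dose <- .superpose(regimen, t_k, m$ka, m$kel, m$F)$A_C
      W_k <- wfun[[i]](t_k)
      c_k <- ft4_concentration(max(endo_at(t_k) + A_dose, 0), W_k, p_i)
      y_k <- max(c_k * (1 + m$sigma_prop * stats::rnorm(1)), 0.1)
      ft4_meas[k] <- y_k
      pna_k <- min(pna_start[i] + t_k, 1826)
      std <- lookup_target_range(pna_k, table_std)
      if (cf$identity_ranges) {
        rng_low[k] <- std$r_low_std; rng_up[k] <- std$r_up_std
      } else {
        hit <- pool[pool$center == center[i] & pool$era == era[i] &
                      pool$bracket == std$bracket, , drop = FALSE]
        if (!nrow(hit))
          hit <- pool[pool$center == center[i] & pool$era == 1L &
                        pool$bracket == std$bracket, , drop = FALSE]
        rng_low[k] <- hit$low[1]; rng_up[k] <- hit$up[1]
      }
      # titration towards the upper half of the target range (the aim in
      # treated CH infants): step down when the measurement exceeds the
      # upper limit, up when it falls below the target median, two tablet
      # steps when far outside; the baseline visit keeps the start dose
      if (k > 1) {
        new_dose <- dose_v[length(dose_v)]
        if (y_k > std$r_up_std)
          new_dose <- new_dose -
            cf$dose_step * (1 + (y_k > 1.3 * std$r_up_std))
        if (y_k < std$p50)
          new_dose <- new_dose +
            cf$dose_step * (1 + (y_k < 0.7 * std$r_low_std))
        new_dose <- min(max(new_dose, cf$dose_min), cf$dose_max)
        if (new_dose != dose_v[length(dose_v)]) {
          dose_t <- c(dose_t, t_k)
          dose_v <- c(dose_v, new_dose)
        }
      }
    }
    w_obs <- wfun[[i]](tv)
    if (!cf$identity_ranges && cf$weight_missing_prob > 0) {
      drop_w <- stats::runif(length(tv)) < cf$weight_missing_prob
      drop_w[1] <- FALSE
      if (sum(!drop_w) >= 2) w_obs[drop_w] <- NA
    }
    if (!cf$identity_ranges && cf$range_missing_prob > 0) {
      drop_r <- stats::runif(length(tv)) < cf$range_missing_prob
      rng_low[drop_r] <- NA; rng_up[drop_r] <- NA
    }
    if (severity[i] == "unknown") ft4_meas[1] <- NA
    obs_list[[i]] <- data.frame(
      subject_id = ids[i], t = tv, ft4 = ft4_meas,
      ft4_ref_low = rng_low, ft4_ref_up = rng_up,
      tsh = tsh_obs[[i]], weight = w_obs,
      dose_daily = .locf_doses(tv, dose_t, dose_v),
      stringsAsFactors = FALSE)
  }
  subjects <- data.frame(subject_id = ids, sex = sex, ga_weeks = ga,
                         pna_start_days = pna_start, severity = severity,
                         stringsAsFactors = FALSE)
  data <- ft4_dataset(subjects, do.call(rbind, obs_list))
  structure(list(data = data,
                 truth = list(model = m, eta = eta, severity = severity,
                              seed = seed, config = cf)),
            class = "ft4_cohort")
}

# dose in effect as of each visit time (the regimen row recorded at a visit)
.locf_doses <- function(visit_times, dose_t, dose_v) {
  idx <- findInterval(visit_times, dose_t)
  dose_v[pmax(idx, 1)]
}

#' @export
print.ft4_cohort <- function(x, ...) {
  cat("Synthetic CH cohort (seed ", x$truth$seed, ")\n", sep = "")
  print(x$data)
  cat(sprintf("  truth: kendo = %g, fV = %g, betaW = %g, wref = %.3g kg\n",
              x$truth$model$kendo, x$truth$model$fV, x$truth$model$betaW,
              x$truth$model$wref))
  invisible(x)
}
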
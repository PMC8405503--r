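#' Structural pharmacokinetic parameters
#'
#' Parameters of the one-compartment oral-absorption model of thyroxine (T4)
#' with residual endogenous production and weight-dependent volume of
#' distribution:
#' \itemize{
#'   \item absorption compartment: `dA_B/dt = In(t) - ka * A_B`, `A_B(0) = 0`,
#'     where `In` delivers `F * 1.29 * dose_j` nmol as a bolus at each daily
#'     dosing time;
#'   \item central compartment: `dA_C/dt = ka * A_B + kendo - kel * A_C`,
#'     `A_C(0) = kendo / kel` (endogenous production in equilibrium before
#'     treatment);
#'   \item observation: `C_FT4 = 0.3 * A_C / V(W)` pmol/l with
#'     `V(W) = fV * (W / wref)^betaW` litres.
#' }
#'
#' Defaults are the published typical values: `ka = 20`/day (maximal
#' absorption peak within hours), `kel = 0.1`/day (plasma T4 half-life about
#' 7 days), `F = 0.6` (oral levothyroxine bioavailability), and the estimated
#' `kendo = 3.66` nmol/day, `fV = 4.96` l, `betaW = 0.753`.
#'
#' @param kendo endogenous zero-order T4 production, nmol/day.
#' @param fV multiplicative volume factor, litres at the reference weight.
#' @param betaW allometric power exponent on body weight (dimensionless).
#' @param ka first-order absorption rate, 1/day.
#' @param kel first-order elimination rate, 1/day.
#' @param F oral bioavailability, fraction in (0, 1].
#' @param wref reference body weight, kg (the median body weight of the
#'   population under study; 8 kg default is representative of a cohort
#'   followed from birth to two years).
#' @return object of class `pk_parameters`.
#' @export
pk_parameters <- function(kendo = 3.66, fV = 4.96, betaW = 0.753,
                          ka = 20, kel = 0.1, F = 0.6, wref = 8) {
  stopifnot(kendo >= 0, fV > 0, ka > 0, kel > 0, F > 0, F <= 1, wref > 0)
  structure(list(kendo = kendo, fV = fV, betaW = betaW, ka = ka, kel = kel,
                 F = F, wref = wref),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("T4 structural PK parameters\n")
  cat(sprintf("  ka    = %g /day   kel = %g /day   F = %g\n", x$ka, x$kel, x$F))
  cat(sprintf("  kendo = %g nmol/day\n", x$kendo))
  cat(sprintf("  V(W)  = %g * (W/%g)^%g l\n", x$fV, x$wref, x$betaW))
  invisible(x)
}

#' Convert a levothyroxine dose from mcg/day to nmol/day
#'
#' Multiplies by the fixed conversion factor 1.29 (molecular weight of
#' thyroxine 776.9 g/mol).  The printed factor, not the recomputed
#' `1000/776.9 = 1.2872`, is used so downstream numbers match the published
#' arithmetic; the discrepancy is below 0.3%.
#'
#' @param dose_mcg dose(s) in mcg/day, >= 0.
#' @return dose(s) in nmol/day.
#' @export
convert_dose_mcg_to_nmol <- function(dose_mcg) {
  if (any(dose_mcg < 0, na.rm = TRUE)) stop("dose must be non-negative")
  dose_mcg * 1.29
}

#' Volume of distribution at a given body weight
#'
#' `V(W) = fV * (W / wref)^betaW` litres.
#'
#' @param W body weight(s), kg, > 0.
#' @param params a [pk_parameters()] object.
#' @return volume(s) in litres.
#' @export
volume_of_distribution <- function(W, params) {
  if (any(W <= 0, na.rm = TRUE)) stop("body weight must be positive")
  params$fV * (W / params$wref)^params$betaW
}

#' Pre-treatment equilibrium amount of T4
#'
#' The central compartment starts at, and without dosing always returns to,
#' `kendo / kel` nmol: the disease cannot be cured, only substituted.
#'
#' @param params a [pk_parameters()] object.
#' @return equilibrium amount, nmol.
#' @export
baseline_amount <- function(params) params$kendo / params$kel

#' Expand a daily dose regimen into individual dosing events
#'
#' A regimen row `(t, dose_daily)` holds from its time until the next row
#' (last-observation-carried-forward, as doses are recorded at clinic visits).
#' Expansion produces one bolus event per day: at `t_j`, `t_j + 1`, ... up to
#' `horizon`.
#'
#' @param times numeric vector of regimen row times (days, non-negative,
#'   strictly increasing).
#' @param doses daily doses (mcg/day, > 0) valid from the matching time.
#' @param horizon last day (inclusive) to expand to.
#' @return data.frame with columns `t` and `dose` (mcg/day), one row per
#'   daily administration.
#' @export
expand_regimen <- function(times, doses, horizon) {
  stopifnot(length(times) == length(doses))
  if (!length(times)) return(data.frame(t = numeric(0), dose = numeric(0)))
  ok <- !is.na(doses)
  times <- times[ok]; doses <- doses[ok]
  if (!length(times)) return(data.frame(t = numeric(0), dose = numeric(0)))
  if (is.unsorted(times, strictly = TRUE))
    stop("regimen times must be strictly increasing")
  if (any(times < 0)) stop("regimen times must be non-negative")
  if (any(doses <= 0)) stop("doses must be positive")
  ev_t <- numeric(0); ev_d <- numeric(0)
  ends <- c(times[-1], horizon + 1)
  for (k in seq_along(times)) {
    if (ends[k] <= times[k]) next
    tk <- seq(times[k], min(ends[k] - 1e-9, horizon), by = 1)
    ev_t <- c(ev_t, tk)
    ev_d <- c(ev_d, rep(doses[k], length(tk)))
  }
  data.frame(t = ev_t, dose = ev_d)
}

# superposition sums for bolus inputs; returns list(A_B, A_C_dose) at `times`
# amounts are in nmol; events: data.frame(t, dose[mcg/day])
.superpose <- function(events, times, ka, kel, F) {
  nT <- length(times)
  A_B <- numeric(nT)
  A_C <- numeric(nT)
  if (!nrow(events)) return(list(A_B = A_B, A_C = A_C))
  amt <- F * convert_dose_mcg_to_nmol(events$dose)
  for (i in seq_len(nT)) {
    dt <- times[i] - events$t
    on <- dt >= 0
    if (!any(on)) next
    dti <- dt[on]; ai <- amt[on]
    A_B[i] <- sum(ai * exp(-ka * dti))
    if (abs(ka - kel) > 1e-9 * max(ka, kel)) {
      A_C[i] <- sum(ai * ka / (ka - kel) * (exp(-kel * dti) - exp(-ka * dti)))
    } else {
      # equal-rate limit of the biexponential term
      A_C[i] <- sum(ai * ka * dti * exp(-ka * dti))
    }
  }
  list(A_B = A_B, A_C = A_C)
}

#' Analytic simulation of T4 amounts under a dosing regimen
#'
#' Exact solution of the linear two-compartment system by superposition of
#' single-dose responses:
#' `A_C(t) = kendo/kel + sum over doses of F * 1.29 * dose_j * ka/(ka - kel) *
#' (exp(-kel (t - t_j)) - exp(-ka (t - t_j)))`, with the analogous
#' single-exponential sum for the absorption compartment.  The degenerate
#' case `ka = kel` uses the analytic limit `amt * ka * dt * exp(-ka * dt)`
#' rather than failing, so parameter samplers may propose near-equal rates.
#'
#' @param params a [pk_parameters()] object.
#' @param regimen data.frame of daily bolus events with columns `t` (days)
#'   and `dose` (mcg/day), e.g. from [expand_regimen()].  An empty regimen
#'   leaves the system at its endogenous equilibrium.
#' @param times sorted non-negative times (days) at which to evaluate.
#' @return data.frame with columns `t`, `A_B`, `A_C` (nmol).
#' @seealso [simulate_amounts_numeric()] for the independent ODE-integration
#'   cross-check.
#' @export
simulate_amounts <- function(params, regimen, times) {
  stopifnot(inherits(params, "pk_parameters"))
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted")
  if (is.null(regimen) || !nrow(regimen))
    regimen <- data.frame(t = numeric(0), dose = numeric(0))
  sp <- .superpose(regimen, times, params$ka, params$kel, params$F)
  data.frame(t = times, A_B = sp$A_B, A_C = baseline_amount(params) + sp$A_C)
}

#' Numeric ODE integration of the T4 amount system
#'
#' Independent verification path for [simulate_amounts()]: integrates the
#' absorption/central compartment ODEs with `deSolve::lsoda`, adding
#' `F * 1.29 * dose_j` nmol to the absorption compartment as a bolus event at
#' each dosing time.  Shares no exponential-superposition code with the
#' analytic solver.
#'
#' @inheritParams simulate_amounts
#' @param rtol,atol integration tolerances.
#' @return data.frame with columns `t`, `A_B`, `A_C` (nmol).
#' @export
simulate_amounts_numeric <- function(params, regimen, times,
                                     rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "pk_parameters"))
  if (is.null(regimen) || !nrow(regimen))
    regimen <- data.frame(t = numeric(0), dose = numeric(0))
  rhs <- function(t, y, p) {
    list(c(A_B = -p$ka * y[["A_B"]],
           A_C = p$ka * y[["A_B"]] + p$kendo - p$kel * y[["A_C"]]))
  }
  y0 <- c(A_B = 0, A_C = baseline_amount(params))
  ev <- NULL
  if (nrow(regimen)) {
    ev <- data.frame(var = "A_B", time = regimen$t,
                     value = params$F * convert_dose_mcg_to_nmol(regimen$dose),
                     method = "add")
    ev <- ev[order(ev$time), ]
  }
  grid <- sort(unique(c(0, times, if (!is.null(ev)) ev$time)))
  sol <- deSolve::lsoda(y0, grid, rhs, params, rtol = rtol, atol = atol,
                        events = if (!is.null(ev)) list(data = ev),
                        maxsteps = 50000)
  idx <- match(times, sol[, "time"])
  data.frame(t = times, A_B = sol[idx, "A_B"], A_C = sol[idx, "A_C"])
}

#' FT4 concentration from a central T4 amount
#'
#' `C_FT4 = 0.3 * A_C / V(W)` pmol/l.  The constant 0.3 is the free fraction
#' of plasma T4 (0.03%) times the nmol-to-pmol conversion (1000).
#'
#' @param A_C central compartment amount(s), nmol, >= 0.
#' @param W body weight(s), kg.
#' @param params a [pk_parameters()] object.
#' @return FT4 concentration(s), pmol/l.
#' @export
ft4_concentration <- function(A_C, W, params) {
  if (any(A_C < 0, na.rm = TRUE)) stop("A_C must be non-negative")
  0.3 * A_C / volume_of_distribution(W, params)
}

#' Simulate an FT4 concentration profile
#'
#' Composes [simulate_amounts()] with [ft4_concentration()], evaluating the
#' weight trajectory at each observation time.  Body weight affects only the
#' observed concentration (through the volume of distribution), never the
#' amount kinetics: elimination is amount-based.
#'
#' @inheritParams simulate_amounts
#' @param weight either a single weight (kg) or a function of time returning
#'   weight in kg (e.g. from [interpolate_trajectory()]).
#' @return data.frame with columns `t`, `A_C`, `weight`, `ft4` (pmol/l).
#' @export
simulate_ft4_profile <- function(params, regimen, weight, times) {
  am <- simulate_amounts(params, regimen, times)
  w <- if (is.function(weight)) weight(times) else rep(weight, length(times))
  data.frame(t = times, A_C = am$A_C, weight = w,
             ft4 = ft4_concentration(am$A_C, w, params))
}
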
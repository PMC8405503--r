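#' Population model specification for FT4 dynamics
#'
#' Bundles the structural typical values, the fixed constants, the log-normal
#' inter-individual variability (IIV) standard deviations, the proportional
#' residual error magnitude and an optional TSH feedback specification.
#' Individual parameters are `theta_i = theta_pop * exp(eta_i)` with
#' `eta_i ~ N(0, omega^2)` (diagonal covariance); observations follow
#' `y = C * (1 + sigma_prop * eps)` with standard-normal `eps`.
#'
#' `ka`, `kel` and `F` are fixed constants by default (not estimated, no
#' IIV): absorption and elimination rates are not identifiable from sparse
#' routine FT4 sampling, so they are pinned to literature-supported values
#' (see [pk_parameters()]).
#'
#' @param kendo,fV,betaW typical values of the endogenous production rate
#'   (nmol/day), volume factor (l) and allometric exponent.
#' @param ka,kel,F fixed constants (1/day, 1/day, fraction).
#' @param wref reference weight, kg; `NULL` means "use the median observed
#'   body weight of the dataset being fitted or generated".
#' @param omega named numeric vector of IIV standard deviations (log scale)
#'   for `kendo`, `fV`, `betaW`; a zero switches that random effect off.
#' @param sigma_prop proportional residual error magnitude (> 0).
#' @param feedback optional [tsh_feedback()] making `kendo` TSH-dependent.
#' @return object of class `ft4_model`.
#' @export
ft4_model <- function(kendo = 3.66, fV = 4.96, betaW = 0.753,
                      ka = 20, kel = 0.1, F = 0.6, wref = NULL,
                      omega = c(kendo = 1.12, fV = 0.249, betaW = 0.404),
                      sigma_prop = 0.228, feedback = NULL) {
  om <- c(kendo = 0, fV = 0, betaW = 0)
  om[names(omega)] <- omega
  stopifnot(kendo > 0, fV > 0, betaW > 0, ka > 0, kel > 0,
            F > 0, F <= 1, all(om >= 0), sigma_prop > 0)
  if (!is.null(feedback)) stopifnot(inherits(feedback, "tsh_feedback"))
  structure(list(kendo = kendo, fV = fV, betaW = betaW, ka = ka, kel = kel,
                 F = F, wref = wref, omega = om, sigma_prop = sigma_prop,
                 feedback = feedback),
            class = "ft4_model")
}

#' @export
print.ft4_model <- function(x, ...) {
  cat("FT4 population model\n")
  cat(sprintf("  typical values: kendo = %g nmol/day, fV = %g l, betaW = %g\n",
              x$kendo, x$fV, x$betaW))
  cat(sprintf("  fixed: ka = %g /day, kel = %g /day, F = %g, wref = %s kg\n",
              x$ka, x$kel, x$F,
              if (is.null(x$wref)) "median(data)" else format(x$wref)))
  cat(sprintf("  IIV sd (log scale): kendo %g, fV %g, betaW %g\n",
              x$omega["kendo"], x$omega["fV"], x$omega["betaW"]))
  cat(sprintf("  proportional residual error: %g\n", x$sigma_prop))
  if (!is.null(x$feedback))
    cat(sprintf("  TSH feedback: %s coupling, f = %s\n",
                x$feedback$coupling, x$feedback$f))
  invisible(x)
}

# pk_parameters for one individual given eta = c(kendo, fV, betaW)
.individual_params <- function(model, eta, wref) {
  pk_parameters(kendo = model$kendo * exp(eta[1]),
                fV = model$fV * exp(eta[2]),
                betaW = model$betaW * exp(eta[3]),
                ka = model$ka, kel = model$kel, F = model$F, wref = wref)
}

#' Deterministic FT4 predictions for one subject
#'
#' Evaluates the structural model with individual parameters
#' `theta_i = theta_pop * exp(eta)` at the subject's observation times,
#' given their dose regimen and weight trajectory.  `eta = c(0, 0, 0)` gives
#' the typical-subject (population) prediction.
#'
#' @param model an [ft4_model()].
#' @param eta numeric length-3 random-effect vector `(kendo, fV, betaW)`.
#' @param dose_times,doses the subject's recorded regimen rows (the dose
#'   holds until the next row).
#' @param weight single weight (kg) or function of time.
#' @param times observation times, days.
#' @param tsh optional function of time returning TSH (mU/l), required when
#'   the model carries a TSH feedback.
#' @param wref reference weight; defaults to the model's (must be set).
#' @return numeric vector of FT4 predictions, pmol/l.
#' @export
individual_prediction <- function(model, eta, dose_times, doses, weight,
                                  times, tsh = NULL, wref = model$wref) {
  stopifnot(inherits(model, "ft4_model"))
  if (is.null(wref)) stop("wref must be set for prediction")
  horizon <- if (length(times)) max(times) else 0
  regimen <- expand_regimen(dose_times, doses, horizon)
  p <- .individual_params(model, eta, wref)
  if (is.null(model$feedback)) {
    prof <- simulate_ft4_profile(p, regimen, weight, times)
    return(prof$ft4)
  }
  if (is.null(tsh)) stop("model has TSH feedback: a tsh trajectory is required")
  days <- seq(0, ceiling(horizon), by = 1)
  prod_daily <- kendo_with_feedback(p$kendo, tsh(days), model$feedback)
  e_endo <- .endo_response(prod_daily, p$kel, times)
  sp <- .superpose(regimen, times, p$ka, p$kel, p$F)
  w <- if (is.function(weight)) weight(times) else rep(weight, length(times))
  ft4_concentration(pmax(e_endo + sp$A_C, 0), w, p)
}

# central-compartment response to a daily piecewise-constant production
# series prod_daily (value for day d applies on [d, d+1)), starting in
# equilibrium with the day-0 production; evaluated at `times`
.endo_response <- function(prod_daily, kel, times) {
  e <- exp(-kel)
  targ <- prod_daily / kel
  n_days <- length(prod_daily)
  # E at integer day boundaries 0, 1, ..., n_days - 1
  E <- stats::filter(targ[-n_days] * (1 - e), e, method = "recursive",
                     init = targ[1])
  E_days <- c(targ[1], as.numeric(E))
  d <- pmin(floor(times), n_days - 1)
  frac <- times - d
  targ_d <- targ[d + 1]
  targ_d + (E_days[d + 1] - targ_d) * exp(-kel * frac)
}
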
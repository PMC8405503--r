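#' Power-model covariate effect on a parameter
#'
#' Continuous covariates act on model parameters through the power model
#' `theta_i = theta_pop * (cov_value / cov_ref)^beta`: the individual
#' parameter equals the typical value at the reference covariate value, with
#' `beta` quantifying the strength of the relationship.
#'
#' @param theta_pop population (typical) parameter value.
#' @param cov_value individual covariate value(s), > 0.
#' @param cov_ref reference covariate value, > 0.
#' @param beta power exponent.
#' @return individual parameter value(s).
#' @export
apply_power_covariate <- function(theta_pop, cov_value, cov_ref, beta) {
  if (cov_ref <= 0) stop("cov_ref must be positive")
  if (any(cov_value <= 0, na.rm = TRUE)) stop("covariate value must be positive")
  theta_pop * (cov_value / cov_ref)^beta
}

#' Categorical covariate effect on a parameter
#'
#' Categorical (non-time-varying) covariates act additively on the log of a
#' log-normally distributed parameter, i.e. multiplicatively as
#' `theta_pop * exp(beta_category)` with `beta = 0` for the reference
#' category.  This is the standard convention for parameters with log-normal
#' inter-individual variability.
#'
#' @param theta_pop population (typical) parameter value.
#' @param category character vector of category labels.
#' @param betas named numeric vector of effects for the non-reference
#'   categories; the reference category is whichever label is absent from
#'   `names(betas)` (effect 0).
#' @param reference label of the reference category.
#' @return individual parameter value(s).
#' @export
apply_categorical_covariate <- function(theta_pop, category, betas,
                                        reference = "reference") {
  known <- c(reference, names(betas))
  bad <- setdiff(unique(category), known)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "))
  b <- ifelse(category == reference, 0, betas[category])
  theta_pop * exp(unname(b))
}

#' Categorize a TSH value
#'
#' Two groupings are used when testing TSH effects on the endogenous T4
#' production rate: `scheme = "two"` splits at 3 mU/l (the average of the
#' median target reference range: category 1 `TSH < 3`, category 2
#' `TSH >= 3`); `scheme = "three"` splits at 1 and 10 mU/l (roughly the
#' average lower/upper target limits: category 1 `TSH < 1`, category 2
#' `1 <= TSH < 10`, category 3 `TSH >= 10`).  Cut points are right-closed at
#' the threshold (`>=`), making the categorization right-continuous.
#'
#' @param tsh TSH value(s), mU/l, >= 0.
#' @param scheme `"two"` or `"three"`.
#' @return integer category index (1-based).
#' @export
#' @examples
#' tsh_category(c(2.9, 3), "two")      # 1, 2
#' tsh_category(c(0.9, 1, 10, 267), "three")  # 1, 2, 3, 3
tsh_category <- function(tsh, scheme = c("two", "three")) {
  scheme <- match.arg(scheme)
  if (any(tsh < 0, na.rm = TRUE)) stop("TSH must be non-negative")
  cuts <- if (scheme == "two") 3 else c(1, 10)
  findInterval(tsh, cuts) + 1L
}

#' Specify a TSH feedback on the endogenous production rate
#'
#' Low FT4 raises TSH, which should stimulate residual thyroid T4 production;
#' this machinery lets the endogenous production rate `kendo` vary with the
#' (interpolated, time-varying) TSH.  Couplings:
#' \describe{
#'   \item{`"categorical"`}{`kendo + beta1` (and `+ beta2` for a third
#'     category) per [tsh_category()] group; `betas` has one element per
#'     non-reference category.}
#'   \item{`"multiplicative"`}{`kendo * f(TSH)`.}
#'   \item{`"additive"`}{`kendo + beta3 * f(TSH)`.}
#' }
#' The transform `f` is one of `"identity"` (`f = TSH`), `"power_ratio"`
#' (`f = (TSH/tsh_ref)^beta`), `"log"` (`f = log TSH`) or `"log_power_ratio"`
#' (`f = (log TSH / log tsh_ref)^beta`); natural logarithms.  TSH below the
#' quantification floor 0.005 mU/l is clamped there before any logarithm.
#' Every form reduces to plain `kendo` when its coefficients are zero (for
#' `"multiplicative"`, when the exponent makes `f` identically 1), the
#' nesting required for likelihood-ratio testing.
#'
#' @param coupling `"categorical"`, `"multiplicative"` or `"additive"`.
#' @param f `"identity"`, `"power_ratio"`, `"log"`, `"log_power_ratio"`.
#' @param scheme TSH grouping for the categorical coupling (see
#'   [tsh_category()]).
#' @param betas coefficients: per-category offsets (categorical) or `beta3`
#'   (additive); ignored for pure multiplicative power forms.
#' @param beta exponent of the ratio forms.
#' @param tsh_ref reference TSH, mU/l, for the ratio forms (no canonical
#'   default exists; it must be supplied when a ratio form is used).
#' @return object of class `tsh_feedback`.
#' @export
tsh_feedback <- function(coupling = c("additive", "multiplicative",
                                      "categorical"),
                         f = c("identity", "power_ratio", "log",
                               "log_power_ratio"),
                         scheme = c("two", "three"),
                         betas = 0, beta = 1, tsh_ref = NULL) {
  coupling <- match.arg(coupling)
  f <- match.arg(f)
  scheme <- match.arg(scheme)
  if (f %in% c("power_ratio", "log_power_ratio")) {
    if (is.null(tsh_ref) || tsh_ref <= 0)
      stop("tsh_ref (> 0) is required for ratio forms")
    if (f == "log_power_ratio" && abs(log(tsh_ref)) < 1e-12)
      stop("tsh_ref = 1 makes log(tsh_ref) zero in the ratio denominator")
  }
  if (coupling == "categorical") {
    n_needed <- if (scheme == "two") 1L else 2L
    if (length(betas) != n_needed)
      stop("categorical coupling with scheme '", scheme, "' needs ",
           n_needed, " beta(s)")
  }
  structure(list(coupling = coupling, f = f, scheme = scheme,
                 betas = as.numeric(betas), beta = beta, tsh_ref = tsh_ref),
            class = "tsh_feedback")
}

.tsh_floor <- 0.005  # limit of quantification, mU/l

.f_tsh <- function(tsh, spec) {
  tsh <- pmax(tsh, .tsh_floor)
  switch(spec$f,
         identity = tsh,
         power_ratio = (tsh / spec$tsh_ref)^spec$beta,
         log = log(tsh),
         log_power_ratio = (log(tsh) / log(spec$tsh_ref))^spec$beta)
}

#' Endogenous production rate under TSH feedback
#'
#' Evaluates the coupling specified by [tsh_feedback()] at given TSH
#' value(s).  Additive couplings can drive the production rate negative for
#' negative coefficients; such values are floored at 0 with a warning, since
#' a production rate cannot be negative.
#'
#' @param kendo baseline endogenous production rate, nmol/day.
#' @param tsh TSH value(s), mU/l.
#' @param spec a [tsh_feedback()] object (or `NULL` for no feedback).
#' @return adjusted production rate(s), nmol/day.
#' @export
kendo_with_feedback <- function(kendo, tsh, spec) {
  if (is.null(spec)) return(rep(kendo, length(tsh)))
  stopifnot(inherits(spec, "tsh_feedback"))
  out <- switch(spec$coupling,
    categorical = {
      cat_idx <- tsh_category(tsh, spec$scheme)
      offs <- c(0, spec$betas)
      kendo + offs[cat_idx]
    },
    multiplicative = kendo * .f_tsh(tsh, spec),
    additive = kendo + spec$betas[1] * .f_tsh(tsh, spec))
  if (any(out < 0)) {
    warning("TSH feedback drove the production rate negative; floored at 0")
    out <- pmax(out, 0)
  }
  out
}

#' Interpolating function through sparse longitudinal support points
#'
#' Builds a monotone shape-preserving piecewise-cubic (Fritsch-Carlson)
#' interpolant through `(times, values)` with constant extrapolation beyond
#' the support range.  On each interval the interpolant stays within the
#' bracketing support values, so monotone data give a monotone curve with no
#' overshoot and positive supports give a positive interpolant — the
#' behaviour wanted for imputing daily body-weight (growth curves) and TSH
#' values between clinic visits.
#'
#' @param times support times, days, strictly increasing.
#' @param values support values, > 0.
#' @return a function of time; with fewer than 2 support points a constant
#'   function is returned with a warning.
#' @export
interpolate_trajectory <- function(times, values) {
  keep <- !is.na(values) & !is.na(times)
  times <- times[keep]; values <- values[keep]
  if (length(times) < 2) {
    warning("fewer than 2 support points; using a constant trajectory")
    v <- if (length(values)) values[1] else NA_real_
    return(function(t) rep(v, length(t)))
  }
  if (is.unsorted(times, strictly = TRUE))
    stop("support times must be strictly increasing")
  if (any(values <= 0)) stop("support values must be positive")
  fun <- stats::splinefun(times, values, method = "monoH.FC")
  lo <- min(times); hi <- max(times)
  function(t) fun(pmin(pmax(t, lo), hi))
}

#' Impute daily values by shape-preserving interpolation
#'
#' Evaluates [interpolate_trajectory()] on the daily grid `0:horizon`.
#'
#' @inheritParams interpolate_trajectory
#' @param horizon last day of the imputed series.
#' @return data.frame with columns `day` and `value`.
#' @export
interpolate_daily <- function(times, values, horizon) {
  f <- interpolate_trajectory(times, values)
  day <- seq(0, horizon, by = 1)
  data.frame(day = day, value = f(day))
}
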
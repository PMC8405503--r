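# predictions at the design's observation rows for a given eta matrix
.design_predictions <- function(design, model, eta) {
  chan <- .endo_channels(design, model)
  idx <- design$idx
  kendo_i <- model$kendo * exp(eta[, 1])
  fV_i <- model$fV * exp(eta[, 2])
  bW_i <- model$betaW * exp(eta[, 3])
  P <- kendo_i[idx] * chan$base + chan$extra + design$S
  V <- fV_i[idx] * exp(bW_i[idx] * design$logw)
  0.3 * P / V
}

#' @export
print.ft4_fit <- function(x, ...) {
  cat("FT4 population model fit",
      if (!x$converged) " (NOT CONVERGED)" else "", "\n", sep = "")
  cat(sprintf("  %d subjects, %d observations (response: %s), wref = %.3g kg\n",
              x$n_subjects, x$n_obs, x$response, x$wref))
  cat(sprintf("  -2 log-likelihood (%s): %.2f\n", x$lik_method, x$minus2ll))
  est <- x$coefficients
  cat("  estimates:\n")
  for (i in seq_len(nrow(est))) {
    cat(sprintf("    %-12s %8.4g", est$parameter[i], est$estimate[i]))
    if (is.finite(est$rse_pct[i]))
      cat(sprintf("  (r.s.e. %.1f%%)", est$rse_pct[i]))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.ft4_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              minus2ll = object$minus2ll,
              shrinkage_pct = object$shrinkage_pct,
              converged = object$converged,
              n_subjects = object$n_subjects, n_obs = object$n_obs,
              response = object$response, wref = object$wref,
              fixed = c(ka = object$model$ka, kel = object$model$kel,
                        F = object$model$F))
  class(out) <- "summary.ft4_fit"
  out
}

#' @export
print.summary.ft4_fit <- function(x, ...) {
  cat("Population estimates (fixed effects), IIV and residual error\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("fixed constants: ka = %g /day, kel = %g /day, F = %g\n",
              x$fixed["ka"], x$fixed["kel"], x$fixed["F"]))
  cat(sprintf("-2LL = %.2f; shrinkage (%%): kendo %.1f, fV %.1f, betaW %.1f\n",
              x$minus2ll, x$shrinkage_pct["kendo"], x$shrinkage_pct["fV"],
              x$shrinkage_pct["betaW"]))
  cat(sprintf("%d subjects, %d observations; converged: %s\n",
              x$n_subjects, x$n_obs, x$converged))
  invisible(x)
}

#' @export
coef.ft4_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$parameter)
}

#' @export
logLik.ft4_fit <- function(object, ...) {
  structure(-object$minus2ll / 2, df = length(object$estimate),
            nobs = object$n_obs, class = "logLik")
}

#' Predictions from a fitted FT4 population model
#'
#' @param object an `ft4_fit`.
#' @param type `"individual"` (conditional on the empirical Bayes random
#'   effects) or `"population"` (typical subject, `eta = 0`).
#' @param ... unused.
#' @return data.frame with `subject_id`, `t`, observed response and `pred`.
#' @export
predict.ft4_fit <- function(object, type = c("individual", "population"),
                            ...) {
  type <- match.arg(type)
  eta <- if (type == "individual") object$eta else
    matrix(0, object$design$n, 3)
  pred <- .design_predictions(object$design, object$model, eta)
  ids <- vapply(object$design$subjects, `[[`, character(1), "id")
  data.frame(subject_id = ids[object$design$idx], t = object$design$t,
             observed = object$design$y, pred = pred,
             stringsAsFactors = FALSE)
}

#' Residuals of a fitted FT4 population model
#'
#' `"iwres"` (default) are individual weighted residuals
#' `(y - c_i) / (sigma_prop * c_i)`, standardized under the proportional
#' residual error model: for an adequate fit they have mean about 0 and
#' variance about 1.  `"raw"` returns `y - c_i`.
#'
#' @param object an `ft4_fit`.
#' @param type `"iwres"` or `"raw"`.
#' @param ... unused.
#' @export
residuals.ft4_fit <- function(object, type = c("iwres", "raw"), ...) {
  type <- match.arg(type)
  pred <- .design_predictions(object$design, object$model, object$eta)
  r <- object$design$y - pred
  if (type == "iwres") r / (object$model$sigma_prop * pred) else r
}

#' Simulate replicate datasets from a fitted model at the observed design
#'
#' Draws new random effects `eta ~ N(0, diag(omega^2))` and proportional
#' residual noise, and evaluates the structural model at the original
#' observation times with the original dose regimens and weight/TSH
#' trajectories.  The backbone of the visual predictive check.
#'
#' @param object an `ft4_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (mandatory for reproducibility).
#' @param ... unused.
#' @return list of numeric vectors, each a simulated response aligned with
#'   the design rows of `predict(object)`.
#' @export
simulate.ft4_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- object$design
  model <- object$model
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    eta <- matrix(0, design$n, 3)
    for (k in 1:3) if (model$omega[k] > 0)
      eta[, k] <- stats::rnorm(design$n, 0, model$omega[k])
    c_pred <- .design_predictions(design, model, eta)
    y <- c_pred * (1 + model$sigma_prop * stats::rnorm(length(c_pred)))
    out[[r]] <- pmax(y, 1e-6)
  }
  out
}

#' Goodness-of-fit tables for a fitted FT4 population model
#'
#' One row per observation with the population prediction (typical subject),
#' the individual prediction (empirical Bayes), and the individual weighted
#' residual; plus a summary with the mean and variance of the weighted
#' residuals (which should be near 0 and 1 under the proportional-error
#' model).
#'
#' @param fit an `ft4_fit`.
#' @return list with `table` (data.frame) and `summary` (named numeric).
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "ft4_fit"))
  pop <- predict(fit, type = "population")
  ind <- predict(fit, type = "individual")
  iwres <- residuals(fit, type = "iwres")
  tab <- data.frame(subject_id = pop$subject_id, t = pop$t,
                    observed = pop$observed, pred_population = pop$pred,
                    pred_individual = ind$pred, iwres = iwres,
                    stringsAsFactors = FALSE)
  list(table = tab,
       summary = c(iwres_mean = mean(iwres), iwres_var = stats::var(iwres)))
}

#' @export
plot.ft4_fit <- function(x, which = c("obs_pred", "iwres_time"), ...) {
  which <- match.arg(which)
  gof <- goodness_of_fit(x)
  tab <- gof$table
  if (which == "obs_pred") {
    rng <- range(c(tab$observed, tab$pred_individual))
    plot(tab$pred_individual, tab$observed, xlab = "Individual prediction",
         ylab = "Observed FT4 (pmol/l)", xlim = rng, ylim = rng,
         pch = 16, col = "#00000066", ...)
    abline(0, 1, col = "grey40")
  } else {
    plot(tab$t, tab$iwres, xlab = "Time since treatment start (days)",
         ylab = "Individual weighted residual", pch = 16,
         col = "#00000066", ...)
    abline(h = 0, col = "grey40")
  }
  invisible(x)
}
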
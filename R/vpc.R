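#' Visual predictive check
#'
#' Simulates `n_replicates` cohorts from the fitted model at the observed
#' design (same subjects, times, doses, weights, TSH), computes the observed
#' and simulated percentiles of the response per time bin, and summarizes the
#' across-replicate spread of each simulated percentile as a confidence band.
#' Bins are equal-count by default because visit density is front-loaded in
#' infancy.  Quantiles use the type-7 (linear interpolation) definition
#' throughout.  Deterministic under `seed`.
#'
#' @param fit an `ft4_fit`.
#' @param n_replicates number of simulated replicate cohorts.
#' @param bins number of time bins (equal observation counts), or a numeric
#'   vector of explicit bin edges in days.
#' @param probs percentiles to track (default 5/50/95).
#' @param ci confidence level of the across-replicate bands.
#' @param seed integer seed for the simulations.
#' @return object of class `ft4_vpc`: per-bin observed percentiles and
#'   simulated percentile bands (`*_lo`, `*_med`, `*_hi`), plus the
#'   simulation matrix dimensions and settings.
#' @export
vpc <- function(fit, n_replicates = 200, bins = 8,
                probs = c(0.05, 0.5, 0.95), ci = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "ft4_fit"))
  t_obs <- fit$design$t
  y_obs <- fit$design$y
  if (length(bins) == 1) {
    edges <- unique(stats::quantile(t_obs, probs = seq(0, 1, length.out =
                                                         bins + 1),
                                    type = 7, names = FALSE))
  } else {
    edges <- sort(unique(bins))
  }
  bin_of <- cut(t_obs, breaks = edges, include.lowest = TRUE)
  keep <- !is.na(bin_of)
  if (any(!keep)) {
    warning(sum(!keep), " observation(s) outside the bin edges were dropped")
    t_obs <- t_obs[keep]; y_obs <- y_obs[keep]; bin_of <- bin_of[keep]
  }
  empty <- !levels(bin_of) %in% unique(as.character(bin_of))
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty bin(s)")
    bin_of <- droplevels(bin_of)
  }
  sims <- simulate(fit, nsim = n_replicates, seed = seed)
  qfun <- function(v, g) {
    do.call(rbind, tapply(v, g, function(z)
      stats::quantile(z, probs = probs, type = 7, names = FALSE),
      simplify = FALSE))
  }
  obs_q <- qfun(y_obs, bin_of)
  sim_q <- array(NA_real_, c(nlevels(bin_of), length(probs), n_replicates))
  for (r in seq_len(n_replicates))
    sim_q[, , r] <- qfun(sims[[r]][keep], bin_of)
  a <- (1 - ci) / 2
  band <- function(stat) apply(sim_q, c(1, 2), stat)
  lo <- band(function(z) stats::quantile(z, a, type = 7, names = FALSE))
  md <- band(stats::median)
  hi <- band(function(z) stats::quantile(z, 1 - a, type = 7, names = FALSE))
  tab <- data.frame(bin = levels(bin_of),
                    t_mid = as.numeric(tapply(t_obs, bin_of, stats::median)),
                    n = as.integer(table(bin_of)))
  for (j in seq_along(probs)) {
    p <- paste0("p", probs[j] * 100)
    tab[[paste0(p, "_obs")]] <- obs_q[, j]
    tab[[paste0(p, "_lo")]] <- lo[, j]
    tab[[paste0(p, "_med")]] <- md[, j]
    tab[[paste0(p, "_hi")]] <- hi[, j]
  }
  structure(list(table = tab, probs = probs, ci = ci,
                 n_replicates = n_replicates, seed = seed,
                 sim_quantiles = sim_q),
            class = "ft4_vpc")
}

#' @export
print.ft4_vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check: %d replicates, %d bins, %g%% bands\n",
              x$n_replicates, nrow(x$table), x$ci * 100))
  cols <- c("bin", "t_mid", "n",
            unlist(lapply(x$probs, function(p)
              paste0("p", p * 100, c("_obs", "_lo", "_hi")))))
  print(x$table[, cols], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fraction of observed percentile points inside their simulated bands
#'
#' Calibration summary of a [vpc()]: for a well-specified model the observed
#' percentiles should fall inside the corresponding simulated confidence
#' bands in most bins.
#'
#' @param x an `ft4_vpc`.
#' @return fraction in `[0, 1]`.
#' @export
vpc_coverage <- function(x) {
  stopifnot(inherits(x, "ft4_vpc"))
  tab <- x$table
  inside <- 0L; total <- 0L
  for (p in paste0("p", x$probs * 100)) {
    ok <- tab[[paste0(p, "_obs")]] >= tab[[paste0(p, "_lo")]] &
      tab[[paste0(p, "_obs")]] <= tab[[paste0(p, "_hi")]]
    inside <- inside + sum(ok); total <- total + length(ok)
  }
  inside / total
}

#' @export
plot.ft4_vpc <- function(x, ...) {
  tab <- x$table
  probs <- x$probs
  ylim <- range(unlist(tab[, -(1:3)]), na.rm = TRUE)
  plot(NA, xlim = range(tab$t_mid), ylim = ylim,
       xlab = "Time since treatment start (days)",
       ylab = "FT4 (pmol/l)", ...)
  shade <- grDevices::adjustcolor("steelblue", 0.25)
  for (j in seq_along(probs)) {
    p <- paste0("p", probs[j] * 100)
    graphics::polygon(c(tab$t_mid, rev(tab$t_mid)),
                      c(tab[[paste0(p, "_lo")]],
                        rev(tab[[paste0(p, "_hi")]])),
                      col = shade, border = NA)
    graphics::lines(tab$t_mid, tab[[paste0(p, "_obs")]], lwd = 2)
  }
  invisible(x)
}
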
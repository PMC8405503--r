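#' Postnatal-age dependent target reference ranges
#'
#' Percentiles (2.5, 50, 97.5) of the target reference range for FT4 (pmol/l)
#' and TSH (mU/l) in neonates and infants, tabulated by postnatal age (PNA)
#' bracket.  These are the ranges every assay-specific measurement is
#' normalized to.  Age brackets in days: "0-1 months" = [0, 30],
#' "1-12 months" = (30, 365], "1-5 years" = (365, 1826]; the half-open-above
#' convention makes the lookup total and unambiguous on [0, 1826] days.
#'
#' @param analyte `"ft4"` (default) or `"tsh"`.
#' @return data.frame with columns `label`, `age_lo`, `age_hi` (days; a
#'   bracket covers `(age_lo, age_hi]`, the first bracket also includes 0)
#'   and `p2_5`, `p50`, `p97_5`.
#' @export
#' @examples
#' target_reference_table()
target_reference_table <- function(analyte = c("ft4", "tsh")) {
  analyte <- match.arg(analyte)
  tab <- data.frame(
    label = c("0-1 months", "1-12 months", "1-5 years"),
    age_lo = c(0, 30, 365),
    age_hi = c(30, 365, 1826),
    stringsAsFactors = FALSE
  )
  if (analyte == "ft4") {
    tab$p2_5 <- c(8.50, 9.17, 10.45)
    tab$p50 <- c(20.10, 15.50, 15.70)
    tab$p97_5 <- c(30.50, 25.28, 22.35)
  } else {
    tab$p2_5 <- c(0.70, 1.12, 0.80)
    tab$p50 <- c(3.50, 2.85, 2.70)
    tab$p97_5 <- c(18.10, 8.21, 6.26)
  }
  tab
}

#' Look up the target reference range for a postnatal age
#'
#' Returns the (2.5th, 97.5th) percentile pair of the age bracket containing
#' `pna_days`.  Vectorized over `pna_days`.
#'
#' @param pna_days postnatal age(s) in days, within the table's coverage
#'   (0 to 1826 days by default).
#' @param table a reference table as returned by [target_reference_table()].
#' @return data.frame with columns `r_low_std`, `r_up_std` (and `p50`).
#' @export
#' @examples
#' lookup_target_range(15)    # 0-1 months bracket: 8.50, 30.50
#' lookup_target_range(200)   # 1-12 months bracket: 9.17, 25.28
lookup_target_range <- function(pna_days, table = target_reference_table()) {
  if (any(!is.finite(pna_days)))
    stop("pna_days must be finite")
  lo <- min(table$age_lo); hi <- max(table$age_hi)
  if (any(pna_days < lo | pna_days > hi))
    stop("postnatal age outside table coverage [", lo, ", ", hi, "] days: ",
         paste(utils::head(pna_days[pna_days < lo | pna_days > hi], 5),
               collapse = ", "))
  # brackets are (age_lo, age_hi], with 0 belonging to the first bracket
  idx <- findInterval(pna_days, c(table$age_lo, hi), left.open = TRUE,
                      rightmost.closed = TRUE)
  idx[pna_days == lo] <- 1L
  data.frame(r_low_std = table$p2_5[idx], r_up_std = table$p97_5[idx],
             p50 = table$p50[idx], bracket = idx)
}

#' Scale normalization (right-skewed data)
#'
#' Rescales a measurement by the ratio of target to assay upper reference
#' limits: `x_norm = x_meas * r_up_std / r_up`.  Appropriate for right-skewed
#' distributions with values piling up near zero, as FT4 does at the start of
#' levothyroxine treatment; never produces negative values from non-negative
#' input.
#'
#' @param x_meas measured value(s), >= 0.
#' @param r_up assay reference-range upper limit (> 0).
#' @param r_up_std target reference-range upper limit.
#' @return normalized value(s).
#' @export
scale_normalize <- function(x_meas, r_up, r_up_std) {
  if (any(r_up <= 0, na.rm = TRUE)) stop("r_up must be positive")
  if (any(x_meas < 0, na.rm = TRUE)) stop("x_meas must be non-negative")
  x_meas * r_up_std / r_up
}

#' Location-scale (Chuang-Stein) normalization (normally distributed data)
#'
#' Affine mapping of a measurement from its assay reference range onto the
#' target range:
#' `x_norm = (x_meas - r_low) * (r_up_std - r_low_std) / (r_up - r_low) + r_low_std`.
#' The output can be negative when `x_meas` lies far below `r_low` relative to
#' a wide assay range; such values are preserved (and flagged downstream), not
#' clamped, unless explicitly requested.
#'
#' @param x_meas measured value(s).
#' @param r_low,r_up assay reference-range limits, `r_low < r_up`.
#' @param r_low_std,r_up_std target reference-range limits.
#' @return normalized value(s); may be negative.
#' @export
location_scale_normalize <- function(x_meas, r_low, r_up, r_low_std, r_up_std) {
  if (any(r_low >= r_up, na.rm = TRUE))
    stop("degenerate assay range: r_low must be < r_up")
  (x_meas - r_low) * (r_up_std - r_low_std) / (r_up - r_low) + r_low_std
}

#' Time-blended scale / location-scale normalization
#'
#' FT4 distributions in treated congenital hypothyroidism transition from
#' right-skewed at treatment start towards normality once substitution is
#' established.  This normalizer therefore blends the two formulas linearly in
#' time: for `t <= ts` it returns
#' `(t/ts) * location_scale + (1 - t/ts) * scale`, and for `t > ts` the pure
#' location-scale result.  The blend is continuous and piecewise-linear in `t`.
#'
#' @inheritParams location_scale_normalize
#' @param t time since treatment start, days (>= 0).
#' @param ts blend threshold in days (default 150, the time by which the
#'   transition towards normality is expected).
#' @param clamp_negative floor negative outputs at 0 (default `FALSE`).
#' @return normalized value(s).
#' @export
#' @examples
#' blended_normalize(10, 9, 29, 8.5, 30.5, t = 75)   # midpoint blend
blended_normalize <- function(x_meas, r_low, r_up, r_low_std, r_up_std,
                              t, ts = 150, clamp_negative = FALSE) {
  if (ts <= 0) stop("ts must be positive")
  if (any(t < 0, na.rm = TRUE)) stop("t must be non-negative")
  ls <- location_scale_normalize(x_meas, r_low, r_up, r_low_std, r_up_std)
  sc <- scale_normalize(x_meas, r_up, r_up_std)
  w <- pmin(t / ts, 1)
  out <- w * ls + (1 - w) * sc
  if (clamp_negative) out <- pmax(out, 0)
  out
}

#' Normalize all FT4 measurements in a dataset
#'
#' Applies [blended_normalize()] row-wise, looking up the target range at the
#' postnatal age of each measurement (`pna_start_days + t`).  Rows whose FT4
#' is present but whose assay reference range is incomplete are left
#' un-normalized and flagged (`ft4_norm_skipped`), mirroring standard practice
#' when ranges are missing; skipping is reported, not an error.
#'
#' @param data an `ft4_dataset`.
#' @param table target reference table ([target_reference_table()]).
#' @param ts blend threshold, days.
#' @param clamp_negative floor negative normalized values at 0.
#' @return the dataset with observation columns `ft4_norm` and
#'   `ft4_norm_skipped` added; attribute `n_skipped` counts skipped rows.
#' @export
normalize_ft4 <- function(data, table = target_reference_table(), ts = 150,
                          clamp_negative = FALSE) {
  stopifnot(inherits(data, "ft4_dataset"))
  ob <- data$observations
  su <- data$subjects
  pna_start <- su$pna_start_days[match(ob$subject_id, su$subject_id)]
  pna_start[is.na(pna_start)] <- 0
  has_ft4 <- !is.na(ob$ft4)
  has_range <- !is.na(ob$ft4_ref_low) & !is.na(ob$ft4_ref_up)
  do <- has_ft4 & has_range
  skip <- has_ft4 & !has_range
  ob$ft4_norm <- NA_real_
  if (any(do)) {
    std <- lookup_target_range(pmin(pna_start[do] + ob$t[do], max(table$age_hi)),
                               table)
    ob$ft4_norm[do] <- blended_normalize(
      ob$ft4[do], ob$ft4_ref_low[do], ob$ft4_ref_up[do],
      std$r_low_std, std$r_up_std, t = ob$t[do], ts = ts,
      clamp_negative = clamp_negative)
  }
  ob$ft4_norm_skipped <- skip
  if (any(skip))
    warning(sum(skip), " FT4 measurement(s) lack an assay reference range ",
            "and were not normalized")
  data$observations <- ob
  attr(data, "n_skipped") <- sum(skip)
  data
}

#' Classify disease severity from baseline FT4
#'
#' Severity of congenital hypothyroidism is defined from the first FT4
#' measurement at diagnosis: severe `FT4 < 5`, moderate `5 <= FT4 < 10`,
#' mild `FT4 >= 10` pmol/l; a missing baseline gives `"unknown"`.
#'
#' @param ft4_baseline baseline FT4 in pmol/l; `NA` allowed.
#' @return character vector of `"severe"`, `"moderate"`, `"mild"`, `"unknown"`.
#' @export
#' @examples
#' classify_severity(c(4.9, 5, 10, NA))
classify_severity <- function(ft4_baseline) {
  if (any(ft4_baseline < 0, na.rm = TRUE))
    stop("baseline FT4 must be non-negative")
  out <- rep("unknown", length(ft4_baseline))
  out[!is.na(ft4_baseline) & ft4_baseline < 5] <- "severe"
  out[!is.na(ft4_baseline) & ft4_baseline >= 5 & ft4_baseline < 10] <- "moderate"
  out[!is.na(ft4_baseline) & ft4_baseline >= 10] <- "mild"
  out
}

.default_windows <- function() {
  list("t = 0" = c(0, 0),
       "0 < t < 50" = c(0 + 1e-9, 50 - 1e-9),
       "100 <= t < 150" = c(100, 150 - 1e-9),
       "last visit" = "last")
}

.window_rows <- function(ob, w) {
  if (identical(w, "last")) {
    last <- tapply(seq_len(nrow(ob)), ob$subject_id, function(i) {
      i <- i[!is.na(ob$ft4[i])]
      if (length(i)) max(i) else NA_integer_
    })
    sort(unname(last[!is.na(last)]))
  } else {
    which(ob$t >= w[1] & ob$t <= w[2] & !is.na(ob$ft4))
  }
}

#' Compare non-normalized and normalized FT4 by time window
#'
#' For each time window, reports the median and interquartile range of the
#' raw and normalized FT4 values, and a rank-based (Wilcoxon) test of the
#' difference between the two sets of values.  Default windows: treatment
#' start (`t = 0`), `0 < t < 50`, `100 <= t < 150` days, and each subject's
#' last measurement.
#'
#' @param data an `ft4_dataset` that has been through [normalize_ft4()].
#' @param windows named list; each element is either `c(lo, hi)` in days
#'   (inclusive) or the string `"last"` for the last FT4 row per subject.
#' @param paired compare paired values (default `TRUE`: the same measurements
#'   before/after normalization).
#' @return data.frame with one row per window: `n`, medians and IQR limits of
#'   both columns, and the Wilcoxon p-value (`NA` for empty windows).
#' @export
summarize_comparison <- function(data, windows = .default_windows(),
                                 paired = TRUE) {
  stopifnot(inherits(data, "ft4_dataset"))
  ob <- data$observations
  if (is.null(ob$ft4_norm)) stop("run normalize_ft4() first")
  one <- function(name, w) {
    i <- .window_rows(ob, w)
    i <- i[!is.na(ob$ft4_norm[i])]
    raw <- ob$ft4[i]; nrm <- ob$ft4_norm[i]
    if (!length(i)) {
      return(data.frame(window = name, n = 0L, median_raw = NA_real_,
                        q25_raw = NA_real_, q75_raw = NA_real_,
                        median_norm = NA_real_, q25_norm = NA_real_,
                        q75_norm = NA_real_, p_value = NA_real_))
    }
    p <- if (length(i) >= 2 && (!paired || any(raw != nrm))) {
      suppressWarnings(stats::wilcox.test(raw, nrm, paired = paired)$p.value)
    } else NA_real_
    qr <- stats::quantile(raw, c(.25, .75), names = FALSE)
    qn <- stats::quantile(nrm, c(.25, .75), names = FALSE)
    data.frame(window = name, n = length(i),
               median_raw = stats::median(raw), q25_raw = qr[1], q75_raw = qr[2],
               median_norm = stats::median(nrm), q25_norm = qn[1],
               q75_norm = qn[2], p_value = p)
  }
  out <- do.call(rbind, Map(one, names(windows), windows))
  rownames(out) <- NULL
  out
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' @param x numeric vector; needs at least 3 non-missing values.
#' @return the bias-adjusted sample skewness
#'   `g1 * sqrt(n (n - 1)) / (n - 2)`.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Distribution diagnostics per time window
#'
#' Reports the sample skewness and a Shapiro-Wilk normality p-value of the
#' (by default raw) FT4 values in each window.  Used to examine the transition
#' of FT4 from a right-skewed distribution at treatment start towards
#' normality under therapy, which motivates the time-blended normalization
#' and its threshold `ts`.  Windows with fewer than 3 values get no skewness;
#' fewer than 8 values, no normality test.
#'
#' @inheritParams summarize_comparison
#' @param value `"ft4"` (default) or `"ft4_norm"`.
#' @return data.frame with columns `window`, `n`, `skewness`, `shapiro_p`.
#' @export
skewness_diagnostic <- function(data, windows = .default_windows(),
                                value = c("ft4", "ft4_norm")) {
  stopifnot(inherits(data, "ft4_dataset"))
  value <- match.arg(value)
  ob <- data$observations
  if (value == "ft4_norm" && is.null(ob$ft4_norm))
    stop("run normalize_ft4() first")
  one <- function(name, w) {
    i <- .window_rows(ob, w)
    v <- ob[[value]][i]
    v <- v[!is.na(v)]
    n <- length(v)
    sk <- if (n >= 3) sample_skewness(v) else NA_real_
    sp <- if (n >= 8 && stats::sd(v) > 0)
      stats::shapiro.test(v)$p.value else NA_real_
    data.frame(window = name, n = n, skewness = sk, shapiro_p = sp)
  }
  out <- do.call(rbind, Map(one, names(windows), windows))
  rownames(out) <- NULL
  out
}
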
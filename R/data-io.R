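#' Canonical column schema for long-format FT4 datasets
#'
#' The package reads and writes one-row-per-subject-time CSV files.  The
#' canonical column names can be remapped (e.g. to NONMEM-style `ID`/`TIME`
#' headers) by passing a modified schema to [read_ft4_dataset()].
#'
#' Canonical columns: `subject_id`, `t` (days since start of levothyroxine
#' treatment), `ft4` (pmol/l), `ft4_ref_low`, `ft4_ref_up` (assay reference
#' range, pmol/l), `tsh` (mU/l), `weight` (kg), `dose_daily` (mcg/day,
#' carried forward between visits), and the per-subject fields `sex`,
#' `ga_weeks`, `pna_start_days`, `severity`.
#'
#' @param ... named overrides, e.g. `ft4_schema(subject_id = "ID", t = "TIME")`.
#' @return named character vector mapping canonical names to file column names.
#' @export
#' @examples
#' ft4_schema(subject_id = "ID", t = "TIME", ft4 = "DV")
ft4_schema <- function(...) {
  schema <- c(
    subject_id = "subject_id", t = "t", ft4 = "ft4",
    ft4_ref_low = "ft4_ref_low", ft4_ref_up = "ft4_ref_up",
    tsh = "tsh", weight = "weight", dose_daily = "dose_daily",
    sex = "sex", ga_weeks = "ga_weeks", pna_start_days = "pna_start_days",
    severity = "severity"
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad))
      stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(over)] <- vapply(over, as.character, character(1))
  }
  schema
}

.obs_cols <- c("subject_id", "t", "ft4", "ft4_ref_low", "ft4_ref_up",
               "tsh", "weight", "dose_daily")
.subj_cols <- c("subject_id", "sex", "ga_weeks", "pna_start_days", "severity")
.num_obs_cols <- c("t", "ft4", "ft4_ref_low", "ft4_ref_up", "tsh", "weight",
                   "dose_daily")

#' Construct a longitudinal FT4 dataset
#'
#' Bundles a subject table (one row per subject: demographics, disease
#' severity) with an observation table (one row per subject-time: FT4 with its
#' assay reference range, TSH, body weight, daily levothyroxine dose) and
#' validates the structural invariants.
#'
#' @param subjects data.frame with columns `subject_id`, `sex`, `ga_weeks`,
#'   `pna_start_days` (postnatal age at treatment start, days), `severity`
#'   (one of `"severe"`, `"moderate"`, `"mild"`, `"unknown"`).
#' @param observations data.frame with columns `subject_id`, `t` (days since
#'   treatment start, `t = 0` is the first dose), `ft4`, `ft4_ref_low`,
#'   `ft4_ref_up`, `tsh`, `weight`, `dose_daily`.  Missing values are `NA`,
#'   never zero.
#' @param validate run [validate_ft4_dataset()] (default `TRUE`).
#' @return object of class `ft4_dataset`.
#' @seealso [read_ft4_dataset()], [validate_ft4_dataset()]
#' @export
ft4_dataset <- function(subjects, observations, validate = TRUE) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  for (col in setdiff(.subj_cols, names(subjects))) {
    subjects[[col]] <- if (col == "severity") "unknown" else NA
  }
  for (col in setdiff(.obs_cols, names(observations)))
    observations[[col]] <- NA_real_
  subjects$subject_id <- as.character(subjects$subject_id)
  observations$subject_id <- as.character(observations$subject_id)
  for (col in .num_obs_cols) observations[[col]] <- as.numeric(observations[[col]])
  subjects$pna_start_days <- as.numeric(subjects$pna_start_days)
  subjects$ga_weeks <- as.numeric(subjects$ga_weeks)
  ord <- order(observations$subject_id, observations$t)
  observations <- observations[ord, , drop = FALSE]
  rownames(observations) <- NULL
  rownames(subjects) <- NULL
  x <- structure(list(subjects = subjects[.subj_cols],
                      observations = observations[.obs_cols]),
                 class = "ft4_dataset")
  if (validate) validate_ft4_dataset(x)
  x
}

#' Validate the structural invariants of an FT4 dataset
#'
#' Checks: every observation's subject is listed in the subject table;
#' per-subject times are non-negative, finite and strictly increasing (no
#' duplicated `(subject_id, t)` rows); `ft4_ref_low < ft4_ref_up` wherever the
#' pair is present; concentrations, weights and doses are strictly positive
#' when present; `pna_start_days >= 0`; severity labels are from the allowed
#' set.  Malformations raise an error naming the offending rows.
#'
#' @param x an `ft4_dataset`.
#' @return `x`, invisibly, if valid.
#' @export
validate_ft4_dataset <- function(x) {
  stopifnot(inherits(x, "ft4_dataset"))
  su <- x$subjects; ob <- x$observations
  if (anyDuplicated(su$subject_id))
    stop("duplicated subject_id in subject table: ",
         paste(unique(su$subject_id[duplicated(su$subject_id)]), collapse = ", "))
  orphan <- setdiff(ob$subject_id, su$subject_id)
  if (length(orphan))
    stop("observations reference unknown subject_id: ",
         paste(orphan, collapse = ", "))
  if (any(!is.finite(ob$t)))
    stop("non-finite time t in observation rows ",
         paste(which(!is.finite(ob$t)), collapse = ", "))
  if (any(ob$t < 0))
    stop("negative time t in observation rows ",
         paste(which(ob$t < 0), collapse = ", "))
  key <- paste(ob$subject_id, ob$t)
  if (anyDuplicated(key))
    stop("duplicated (subject_id, t) observation rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  both <- !is.na(ob$ft4_ref_low) & !is.na(ob$ft4_ref_up)
  if (any(both & ob$ft4_ref_low >= ob$ft4_ref_up))
    stop("ft4_ref_low >= ft4_ref_up in observation rows ",
         paste(which(both & ob$ft4_ref_low >= ob$ft4_ref_up), collapse = ", "))
  for (col in c("ft4", "ft4_ref_low", "ft4_ref_up", "tsh", "weight",
                "dose_daily")) {
    bad <- !is.na(ob[[col]]) & ob[[col]] <= 0
    if (any(bad))
      stop("non-positive ", col, " in observation rows ",
           paste(which(bad), collapse = ", "))
  }
  if (any(!is.na(su$pna_start_days) & su$pna_start_days < 0))
    stop("negative pna_start_days in subject table")
  sev_ok <- su$severity %in% c("severe", "moderate", "mild", "unknown")
  if (!all(sev_ok))
    stop("invalid severity label(s): ",
         paste(unique(su$severity[!sev_ok]), collapse = ", "))
  invisible(x)
}

#' @export
print.ft4_dataset <- function(x, ...) {
  ns <- nrow(x$subjects)
  no <- nrow(x$observations)
  nft4 <- sum(!is.na(x$observations$ft4))
  cat("Longitudinal FT4 dataset\n")
  cat(sprintf("  %d subjects, %d observation rows (%d FT4 measurements)\n",
              ns, no, nft4))
  if (no)
    cat(sprintf("  follow-up: %.0f to %.0f days since treatment start\n",
                min(x$observations$t), max(x$observations$t)))
  sev <- table(factor(x$subjects$severity,
                      levels = c("severe", "moderate", "mild", "unknown")))
  cat("  severity: ", paste(sprintf("%s %d", names(sev), sev), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$observations$ft4_norm))
    cat(sprintf("  normalized FT4 present for %d rows\n",
                sum(!is.na(x$observations$ft4_norm))))
  invisible(x)
}

.parse_num_col <- function(txt, col) {
  txt <- trimws(txt)
  out <- rep(NA_real_, length(txt))
  has <- !is.na(txt) & nzchar(txt) & txt != "NA"
  val <- suppressWarnings(as.numeric(txt[has]))
  if (anyNA(val)) {
    bad <- which(has)[is.na(val)]
    stop("malformed numeric value in column '", col, "', data row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(txt[bad]), collapse = ", "))
  }
  out[has] <- val
  out
}

#' Read a long-format FT4 dataset from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, `.` decimal separator) with one row per
#' subject-time.  Per-subject columns (`sex`, `ga_weeks`, `pna_start_days`,
#' `severity`) may be repeated on every row; the first non-missing value per
#' subject is used.  Empty cells become `NA` (missingness is first-class; no
#' imputation happens at the I/O layer).
#'
#' @param path CSV file path.
#' @param schema column-name mapping from [ft4_schema()]; file columns not in
#'   the schema are ignored, absent optional columns become all-`NA`.
#' @return an `ft4_dataset`.
#' @export
read_ft4_dataset <- function(path, schema = ft4_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  need <- schema[c("subject_id", "t")]
  miss <- need[!need %in% names(raw)]
  if (length(miss))
    stop("required column(s) missing from ", path, ": ",
         paste(miss, collapse = ", "))
  get_col <- function(canon) {
    file_col <- schema[[canon]]
    if (file_col %in% names(raw)) raw[[file_col]] else rep(NA_character_, nrow(raw))
  }
  ob <- data.frame(subject_id = trimws(get_col("subject_id")),
                   stringsAsFactors = FALSE)
  for (col in .num_obs_cols) ob[[col]] <- .parse_num_col(get_col(col), schema[[col]])
  first_per_subject <- function(v, ids) {
    out <- tapply(v, ids, function(z) {
      z <- z[!is.na(z) & (!is.character(z) | nzchar(z))]
      if (length(z)) z[[1]] else NA
    })
    out[match(unique(ids), names(out))]
  }
  ids <- ob$subject_id
  sev <- trimws(get_col("severity"))
  sev[!nzchar(sev)] <- NA_character_
  su <- data.frame(
    subject_id = unique(ids),
    sex = as.character(first_per_subject(trimws(get_col("sex")), ids)),
    ga_weeks = as.numeric(first_per_subject(
      .parse_num_col(get_col("ga_weeks"), schema[["ga_weeks"]]), ids)),
    pna_start_days = as.numeric(first_per_subject(
      .parse_num_col(get_col("pna_start_days"), schema[["pna_start_days"]]), ids)),
    severity = as.character(first_per_subject(sev, ids)),
    stringsAsFactors = FALSE
  )
  su$severity[is.na(su$severity)] <- "unknown"
  su$sex[is.na(su$sex) | !nzchar(su$sex)] <- NA_character_
  ft4_dataset(su, ob)
}

# shortest decimal text that parses back to exactly the same double
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Write an FT4 dataset to CSV
#'
#' Inverse of [read_ft4_dataset()]: writes one row per observation with the
#' subject-level columns repeated.  Numeric values are written with the
#' shortest decimal representation that re-reads to the identical double, so
#' `read_ft4_dataset(write_ft4_dataset(d))` round-trips exactly.  Missing
#' values become empty fields.
#'
#' @param x an `ft4_dataset`.
#' @param path output file path (directory must exist).
#' @return `path`, invisibly.
#' @export
write_ft4_dataset <- function(x, path) {
  stopifnot(inherits(x, "ft4_dataset"))
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  ob <- x$observations
  su <- x$subjects[match(ob$subject_id, x$subjects$subject_id), ]
  out <- data.frame(subject_id = ob$subject_id, stringsAsFactors = FALSE)
  for (col in .num_obs_cols) out[[col]] <- .fmt_num(ob[[col]])
  out$sex <- ifelse(is.na(su$sex), "", su$sex)
  out$ga_weeks <- .fmt_num(su$ga_weeks)
  out$pna_start_days <- .fmt_num(su$pna_start_days)
  out$severity <- su$severity
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
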
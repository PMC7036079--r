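#' Rectangular PK event dataset
#'
#' The analysis dataset follows the rectangular event-record convention used
#' by pharmacometric tools: one row per dose or observation event.
#'
#' Mandatory columns:
#' * `ID` subject identifier;
#' * `TIME` actual time (h), non-negative, non-decreasing within subject;
#' * `AMT` dose amount (mg), `NA` on observation rows;
#' * `RATE` infusion rate (mg/h), `NA` on observation rows;
#' * `DV` observed concentration (mg/L), `NA` on dose rows;
#' * `EVID` 1 = dose, 0 = observation;
#' * `MDV` missing-DV flag (1 on dose rows).
#'
#' Optional columns used when present: `NTIM` (nominal time, VPC binning),
#' `BLQ` (below-LLOQ flag), `CYCLE`, `TAG` (nominal sample label such as
#' `"C1P"`, `"C3T"`, `"EOT"`), and covariate columns (`BWT`, `SEXM`,
#' `DRUG`, ...), constant within subject.
#'
#' @param df a data.frame of event records.
#' @return The validated data.frame with class `pk_dataset`.
#' @export
pk_dataset <- function(df) {
  req <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(df$TIME))
    stop("TIME must be numeric")
  if (any(is.na(df$TIME)))
    stop("non-numeric or missing TIME at row(s) ",
         paste(utils::head(which(is.na(df$TIME)), 5), collapse = ", "))
  if (any(df$TIME < 0)) stop("negative TIME at row(s) ",
                             paste(utils::head(which(df$TIME < 0), 5), collapse = ", "))
  if (!all(df$EVID %in% c(0L, 1L))) stop("EVID must be 0 (observation) or 1 (dose)")
  bad <- df$EVID == 1 & !is.na(df$DV)
  if (any(bad))
    stop("DV present on dose row(s) ", paste(utils::head(which(bad), 5), collapse = ", "))
  bad <- df$EVID == 1 & (is.na(df$AMT) | df$AMT <= 0)
  if (any(bad))
    stop("dose row(s) without positive AMT: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  for (id in unique(df$ID)) {
    tt <- df$TIME[df$ID == id]
    if (is.unsorted(tt))
      stop("TIME not non-decreasing within subject ", id)
  }
  # every post-first-dose observation must have a preceding dose row
  obs <- df$EVID == 0
  if (any(obs)) {
    first_dose <- tapply(ifelse(df$EVID == 1, df$TIME, Inf), df$ID, min)
    fd <- first_dose[as.character(df$ID)]
    orphan <- obs & !is.na(df$DV) & is.infinite(fd)
    if (any(orphan))
      stop("observation without any dose for subject(s) ",
           paste(unique(df$ID[orphan]), collapse = ", "))
  }
  class(df) <- unique(c("pk_dataset", class(df)))
  df
}

#' @export
print.pk_dataset <- function(x, ...) {
  nobs <- sum(x$EVID == 0)
  cat(sprintf("pk_dataset: %d subjects, %d dose records, %d observations\n",
              length(unique(x$ID)), sum(x$EVID == 1), nobs))
  invisible(x)
}

#' Read / write the event dataset as CSV
#'
#' Plain-CSV serialisation of a [pk_dataset()]; missing values are written
#' as `.` following the pharmacometric convention. `write_pk_dataset()` and
#' `read_pk_dataset()` round-trip losslessly.
#'
#' @param path file path.
#' @param ds a [pk_dataset()].
#' @return `read_pk_dataset()` returns a validated [pk_dataset()].
#' @export
read_pk_dataset <- function(path) {
  df <- utils::read.csv(path, na.strings = c(".", "NA"),
                        stringsAsFactors = FALSE)
  if (!nrow(df)) {
    df[] <- lapply(df, as.numeric)  # empty columns read as logical
    for (cl in c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV"))
      if (!cl %in% names(df)) df[[cl]] <- numeric(0)
  }
  if (nrow(df) && any(!vapply(df[c("TIME")], is.numeric, logical(1))))
    stop("non-numeric TIME column in ", path)
  pk_dataset(df)
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = ".")
  invisible(path)
}

#' Flag below-LLOQ observations
#'
#' Adds/refreshes a `BLQ` column: observation rows with `DV < lloq`
#' (strictly) are flagged; values are retained for audit and no rows are
#' removed.
#'
#' @param rec an event data.frame (a full dataset or one subject's records).
#' @param lloq lower limit of quantification (mg/L), > 0.
#' @return `rec` with a logical `BLQ` column.
#' @export
apply_lloq_censoring <- function(rec, lloq) {
  if (lloq <= 0) stop("lloq must be > 0")
  rec$BLQ <- rec$EVID == 0 & !is.na(rec$DV) & rec$DV < lloq
  rec
}

#' Impute missing continuous covariates with the population median
#'
#' Subjects missing a baseline covariate get the median of the observed
#' per-subject values (the least-surprise default for a handful of missing
#' baselines); imputed subjects are flagged in `<cov>_IMP` columns.
#'
#' @param ds a [pk_dataset()].
#' @param covariates character vector of continuous covariate columns.
#' @return The dataset with imputed values and flag columns.
#' @export
impute_missing_covariates <- function(ds, covariates) {
  df <- as.data.frame(ds)
  for (cv in covariates) {
    if (!cv %in% names(df)) stop("no covariate column '", cv, "'")
    ids <- unique(df$ID)
    per_subj <- df[[cv]][match(ids, df$ID)]
    med <- stats::median(per_subj, na.rm = TRUE)
    miss <- is.na(df[[cv]])
    df[[paste0(cv, "_IMP")]] <- as.integer(miss)
    df[[cv]][miss] <- med
  }
  pk_dataset(df)
}

#' Pre-modeling exclusion rules with audit trail
#'
#' Applies the two dataset-construction rules used for body-weight-dosed
#' antibody trough/peak data:
#'
#' 1. first-dose pre-dose samples (observations at or before the subject's
#'    first dose time during cycle 1) whose value exceeds `2 * lloq` are
#'    excluded as discordant carryover/contamination;
#' 2. post-dose observations strictly below `lloq` are excluded (the "M1"
#'    convention for below-quantification data).
#'
#' Dose rows are never removed and the operation is idempotent.
#'
#' @param ds a [pk_dataset()].
#' @param lloq lower limit of quantification (mg/L).
#' @return A list with `dataset` (filtered [pk_dataset()]) and `report`
#'   (class `exclusion_report`: counts, row indices, before/after totals,
#'   and the BLQ fraction of post-dose observations).
#' @examples
#' \donttest{
#' trial <- simulate_trial(trial_design(n_subjects = 5), seed = 1)
#' apply_exclusions(trial, lloq = 0.25)$report
#' }
#' @export
apply_exclusions <- function(ds, lloq) {
  stopifnot(inherits(ds, "pk_dataset"))
  if (lloq <= 0) stop("lloq must be > 0")
  df <- as.data.frame(ds)
  first_dose <- tapply(ifelse(df$EVID == 1, df$TIME, Inf), df$ID, min)
  fd <- as.numeric(first_dose[as.character(df$ID)])
  obs <- df$EVID == 0 & !is.na(df$DV)
  predose1 <- obs & df$TIME <= fd
  postdose <- obs & df$TIME > fd
  excl_a <- which(predose1 & df$DV > 2 * lloq)
  excl_b <- which(postdose & df$DV < lloq)
  drop <- union(excl_a, excl_b)
  n_post <- sum(postdose)
  report <- structure(list(
    n_before = sum(obs),
    n_predose_high = length(excl_a),
    n_blq = length(excl_b),
    rows_predose_high = excl_a,
    rows_blq = excl_b,
    n_after = sum(obs) - length(drop),
    n_postdose = n_post,
    blq_fraction = if (n_post > 0) length(excl_b) / n_post else NA_real_,
    blq_percent = if (n_post > 0)
      sprintf("%.2f%%", 100 * length(excl_b) / n_post) else NA_character_,
    lloq = lloq), class = "exclusion_report")
  out <- if (length(drop)) df[-drop, , drop = FALSE] else df
  rownames(out) <- NULL
  list(dataset = pk_dataset(out), report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("observations before exclusions: %d\n", x$n_before))
  cat(sprintf("  first-dose pre-dose > 2 x LLOQ (%.3g mg/L): %d\n",
              2 * x$lloq, x$n_predose_high))
  cat(sprintf("  post-dose BLQ (< %.3g mg/L, M1): %d", x$lloq, x$n_blq))
  if (!is.na(x$blq_percent))
    cat(sprintf(" (%d of %d post-dose observations; %s)",
                x$n_blq, x$n_postdose, x$blq_percent))
  cat(sprintf("\nobservations after exclusions: %d\n", x$n_after))
  invisible(x)
}

#' Serialise an exclusion report to JSON
#'
#' @param report an `exclusion_report`.
#' @param path output path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
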
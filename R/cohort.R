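## Cohort construction, time-of-death imputation, interval arithmetic and
## percentage-change summaries.

#' Impute the time of death for day-only death estimates
#'
#' Many routine cases carry an estimated day of death but no clock time.
#' The imputation rule is: if the body was admitted to the mortuary on a
#' later calendar day, the time of death is set to 12:00 (noon) on the
#' estimated day of death; if admission happened on the same calendar
#' day, the time of death is set to the midpoint between 00:00 (midnight)
#' of that day and the admission time. Records with a full timestamp
#' (\code{dayOnly = FALSE}) are returned unchanged.
#'
#' @param estimatedDeath \code{POSIXct} (UTC) estimated death time; for
#'   day-only records any time on the correct calendar day (conventionally
#'   midnight) — only the date part is used.
#' @param admission \code{POSIXct} mortuary-admission time.
#' @param dayOnly logical; is the death estimate day-only?
#' @return \code{POSIXct} imputed time of death, never later than
#'   \code{admission}.
#' @examples
#' adm <- as.POSIXct("2020-01-06 08:00", tz = "UTC")
#' imputeTimeOfDeath(as.POSIXct("2020-01-05", tz = "UTC"), adm, TRUE)
#' @export
imputeTimeOfDeath <- function(estimatedDeath, admission, dayOnly) {
  stopifnot(inherits(estimatedDeath, "POSIXct"), inherits(admission, "POSIXct"))
  n <- max(length(estimatedDeath), length(admission), length(dayOnly))
  estimatedDeath <- rep_len(estimatedDeath, n)
  admission <- rep_len(admission, n)
  dayOnly <- rep_len(as.logical(dayOnly), n)
  out <- estimatedDeath
  deathDay <- as.POSIXct(format(estimatedDeath, "%Y-%m-%d"), tz = "UTC")
  admDay <- as.POSIXct(format(admission, "%Y-%m-%d"), tz = "UTC")
  live <- !is.na(dayOnly) & !is.na(estimatedDeath) & !is.na(admission)
  if (any(live & dayOnly & admDay < deathDay))
    stop("invalid chronology: admission earlier than the estimated death day")
  if (any(live & !dayOnly & admission < estimatedDeath))
    stop("invalid chronology: admission earlier than the estimated time of death")
  later <- live & dayOnly & admDay > deathDay
  same <- live & dayOnly & admDay == deathDay
  out[later] <- deathDay[later] + 12 * 3600
  ## midpoint between midnight and admission, on the shared calendar day
  out[same] <- deathDay[same] +
    as.numeric(difftime(admission[same], deathDay[same], units = "secs")) / 2
  out
}

#' Sampling intervals in hours
#'
#' Computes the pre-admission interval (t1 - t0), the pre-autopsy interval
#' (t2 - t0) and the signed sampling interval delta_t = t1 - t2 (negative
#' by construction), all in hours.
#'
#' @param t0,t1,t2 \code{POSIXct} vectors: imputed death, admission
#'   sampling and autopsy sampling times; requires t0 <= t1 < t2.
#' @return \code{DataFrame} with columns \code{pre_admission_h},
#'   \code{pre_autopsy_h}, \code{delta_t_h}.
#' @export
computeIntervals <- function(t0, t1, t2) {
  stopifnot(inherits(t0, "POSIXct"), inherits(t1, "POSIXct"),
            inherits(t2, "POSIXct"))
  live <- !is.na(t1) & !is.na(t2)
  if (any(live & t1 >= t2))
    stop("invalid chronology: t1 must be strictly earlier than t2")
  if (any(live & !is.na(t0) & t0 > t1))
    stop("invalid chronology: t0 must not be later than t1")
  h <- function(a, b) as.numeric(difftime(a, b, units = "hours"))
  DataFrame(pre_admission_h = h(t1, t0),
            pre_autopsy_h = h(t2, t0),
            delta_t_h = h(t1, t2))
}

#' Percentage concentration change between the two sampling times
#'
#' \code{(c2 - c1) / c1 * 100}: negative values are time-dependent
#' concentration decreases between admission (t1) and autopsy (t2).
#'
#' @param c1 concentration at t1; must be > 0.
#' @param c2 concentration at t2.
#' @return percent change, vectorized; NA where either input is NA.
#' @examples
#' percentChange(100, 73)  # -27
#' @export
percentChange <- function(c1, c2) {
  if (any(!is.na(c1) & c1 <= 0))
    stop("percentChange: c1 must be > 0")
  (c2 - c1) / c1 * 100
}

parseStamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  x <- as.character(x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  has <- !is.na(x) & nzchar(x)
  if (any(has)) {
    v <- x[has]
    v <- sub("T", " ", v, fixed = TRUE)
    dateOnly <- !grepl(":", v)
    v[dateOnly] <- paste(v[dateOnly], "00:00:00")
    out[has] <- as.POSIXct(v, tz = "UTC",
                           tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  }
  out
}

#' Construct a PMCohort
#'
#' Builds the cohort container from raw case records. For day-only death
#' estimates t0 is imputed with \code{\link{imputeTimeOfDeath}}; sampling
#' intervals and per-case percentage concentration changes are derived.
#' Records failing the requirements for model fitting (positive
#' concentrations at both time points, t1 strictly before t2) are kept
#' but flagged, with the exclusion reason recorded; percentage changes
#' are still computed whenever both concentrations and both sampling
#' times exist.
#'
#' @param cases a \code{data.frame} (or DataFrame) with columns
#'   \code{case_id}, \code{drug}, \code{c_t1}, \code{c_t2}, \code{t0},
#'   \code{t1}, \code{t2} and optionally \code{t0_day_only} (default
#'   FALSE). Timestamps may be \code{POSIXct} or ISO-8601 strings; a
#'   date-only \code{t0} together with \code{t0_day_only = TRUE} triggers
#'   imputation.
#' @return a \code{\linkS4class{PMCohort}}.
#' @export
PMCohort <- function(cases) {
  cases <- as.data.frame(cases)
  req <- c("case_id", "drug", "c_t1", "c_t2", "t0", "t1", "t2")
  missing <- setdiff(req, names(cases))
  if (length(missing))
    stop("PMCohort: missing columns: ", paste(missing, collapse = ", "))
  if (is.null(cases$t0_day_only)) cases$t0_day_only <- FALSE
  n <- nrow(cases)
  t0 <- parseStamp(cases$t0); t1 <- parseStamp(cases$t1); t2 <- parseStamp(cases$t2)
  dayOnly <- as.logical(cases$t0_day_only)
  imp <- !is.na(dayOnly) & dayOnly & !is.na(t0) & !is.na(t1)
  if (any(imp)) t0[imp] <- imputeTimeOfDeath(t0[imp], t1[imp], TRUE)

  preAdm <- preAut <- deltaT <- rep(NA_real_, n)
  haveT <- !is.na(t1) & !is.na(t2)
  okT <- haveT & t1 < t2
  if (any(okT)) {
    iv <- computeIntervals(t0[okT], t1[okT], t2[okT])
    preAdm[okT] <- iv$pre_admission_h
    preAut[okT] <- iv$pre_autopsy_h
    deltaT[okT] <- iv$delta_t_h
  }
  c1 <- as.numeric(cases$c_t1); c2 <- as.numeric(cases$c_t2)
  okC <- !is.na(c1) & c1 > 0 & !is.na(c2) & c2 > 0
  pct <- rep(NA_real_, n)
  pctOk <- okC & haveT
  pct[pctOk] <- percentChange(c1[pctOk], c2[pctOk])

  reason <- rep(NA_character_, n)
  reason[!okC] <- "non-positive or missing concentration"
  reason[okC & !haveT] <- "missing sampling timestamp"
  reason[okC & haveT & !okT] <- "t1 not earlier than t2"
  valid <- okC & okT
  if (any(!valid))
    message(sum(!valid), " record(s) excluded from model fitting (",
            paste(unique(reason[!valid]), collapse = "; "), ")")
  new("PMCohort", cases = DataFrame(
    case_id = as.character(cases$case_id), drug = as.character(cases$drug),
    c_t1 = c1, c_t2 = c2, t0 = t0, t1 = t1, t2 = t2,
    t0_day_only = dayOnly,
    pre_admission_h = preAdm, pre_autopsy_h = preAut, delta_t_h = deltaT,
    pct_change = pct, model_valid = valid, exclude_reason = reason))
}

#' @describeIn PMCohort accessor: the full case table (DataFrame).
#' @param object,x a \code{PMCohort}.
#' @export
caseData <- function(object) object@cases

#' @describeIn PMCohort drugs present in the cohort.
#' @export
drugNames <- function(object) sort(unique(object@cases$drug))

#' Subset a cohort to one drug's model-ready records
#'
#' @param object a \code{\linkS4class{PMCohort}}.
#' @param drug drug name; NULL keeps all drugs.
#' @param validOnly keep only records eligible for model fitting.
#' @return DataFrame of case records.
#' @export
cohortRecords <- function(object, drug = NULL, validOnly = TRUE) {
  cs <- object@cases
  if (!is.null(drug)) {
    if (!drug %in% cs$drug)
      stop("unknown drug '", drug, "'; cohort contains: ",
           paste(drugNames(object), collapse = ", "))
    cs <- cs[cs$drug == drug, , drop = FALSE]
  }
  if (validOnly) cs <- cs[cs$model_valid, , drop = FALSE]
  cs
}

setMethod("show", "PMCohort", function(object) {
  cs <- object@cases
  cat("PMCohort with", nrow(cs), "case record(s),",
      length(unique(cs$drug)), "drug(s)\n")
  for (d in drugNames(object)) {
    sel <- cs$drug == d
    cat(sprintf("  %-12s n=%d (model-ready %d), median change %+.1f%%\n",
                d, sum(sel), sum(cs$model_valid[sel]),
                median(cs$pct_change[sel], na.rm = TRUE)))
  }
})

setMethod("length", "PMCohort", function(x) nrow(x@cases))

#' Summarize percentage concentration changes per drug
#'
#' Median, minimum, maximum and 5th/95th percentiles of the per-case
#' percentage concentration changes — the statistics drawn as box-whisker
#' plots (whiskers at the 5-95 percent percentile, median inside the
#' box). Percentiles use linear interpolation between order statistics by
#' default (\code{type = 7}, the R default); the method is configurable.
#'
#' @param cohort a \code{\linkS4class{PMCohort}}.
#' @param drug single drug name, or NULL for all drugs in the cohort.
#' @param type quantile algorithm passed to \code{\link[stats]{quantile}}.
#' @return DataFrame with one row per drug and columns \code{drug},
#'   \code{n}, \code{median_pct}, \code{min_pct}, \code{max_pct},
#'   \code{p5_pct}, \code{p95_pct}.
#' @export
summarizeChanges <- function(cohort, drug = NULL, type = 7) {
  stopifnot(is(cohort, "PMCohort"))
  cs <- cohort@cases
  drugs <- if (is.null(drug)) drugNames(cohort) else drug
  rows <- lapply(drugs, function(d) {
    x <- cs$pct_change[cs$drug == d]
    x <- x[!is.na(x)]
    if (!length(x))
      stop("summarizeChanges: no valid percentage changes for drug '", d, "'")
    q <- quantile(x, c(0.05, 0.95), type = type, names = FALSE)
    DataFrame(drug = d, n = length(x), median_pct = median(x),
              min_pct = min(x), max_pct = max(x),
              p5_pct = q[1], p95_pct = q[2])
  })
  do.call(rbind, rows)
}

#' Read / write a cohort CSV
#'
#' The cohort interchange format is a UTF-8 CSV with header and columns
#' \code{case_id, drug, c_t1, c_t2, t0, t1, t2, t0_day_only}; timestamps
#' ISO-8601 (a date-only \code{t0} is allowed when \code{t0_day_only} is
#' TRUE).
#'
#' @param path file path.
#' @return \code{readCohortCsv}: a \code{\linkS4class{PMCohort}}.
#' @export
readCohortCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("c_t1", "c_t2")) df[[col]] <- as.numeric(df[[col]])
  if (!is.null(df$t0_day_only))
    df$t0_day_only <- toupper(df$t0_day_only) %in% c("TRUE", "T", "1")
  PMCohort(df)
}

#' @rdname readCohortCsv
#' @param cohort a \code{\linkS4class{PMCohort}}.
#' @return \code{writeCohortCsv}: the path, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  stopifnot(is(cohort, "PMCohort"))
  cs <- as.data.frame(cohort@cases[, c("case_id", "drug", "c_t1", "c_t2",
                                       "t0", "t1", "t2", "t0_day_only")])
  fmt <- function(t, dateOnly = rep(FALSE, length(t)))
    ifelse(is.na(t), "",
           ifelse(dateOnly, format(t, "%Y-%m-%d", tz = "UTC"),
                  format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")))
  cs$t0 <- fmt(cohort@cases$t0)
  cs$t1 <- fmt(cohort@cases$t1)
  cs$t2 <- fmt(cohort@cases$t2)
  write.csv(cs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
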
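# Domain types for structured EHR extracts: coded diagnoses, labs, ECGs,
# echocardiograms, hospitalizations, claims, and the patient record tying
# them together.  Objects are plain lists with class tags; constructors
# validate invariants and `validate_patient_record()` re-checks a whole
# record (used by the JSON-lines reader).

CODE_SYSTEMS <- c("ICD9CM", "IMO", "ICD9PROC", "CPT4")
CLAIM_PLACES <- c("OFFICE", "INPATIENT", "ED", "OTHER")

#' Parse a timestamp or date string
#'
#' Accepts `"YYYY-MM-DD"` or ISO-8601 `"YYYY-MM-DDTHH:MM:SS"` (a space
#' separator is also tolerated) and returns a timezone-naive `POSIXct`
#' (stored as UTC).  Dates compare at day precision via [as.Date()].
#'
#' @param x character vector, `Date`, or `POSIXct`.
#' @return `POSIXct` vector in UTC.
#' @keywords internal
parse_datetime <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  if (inherits(x, "Date")) return(as.POSIXct(format(x), tz = "UTC"))
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) stop("unparseable timestamp: ", paste(x[is.na(out)], collapse = ", "))
  out
}

parse_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(parse_datetime(x))
}

#' Create a coded diagnosis or procedure entry
#'
#' @param system one of `"ICD9CM"`, `"IMO"`, `"ICD9PROC"`, `"CPT4"`.
#' @param code the code string; normalized to uppercase with whitespace
#'   trimmed.  ICD-9-CM codes must be `ddd` or `ddd.d(d)`; IMO terms may
#'   append uppercase letters (e.g. `"410.90CP"`); procedure codes are
#'   `dd.d(d)`; CPT-4 codes are 5 digits.
#' @param position rank in the discharge diagnosis list (1 = primary).
#' @return a `coded_diagnosis` object.
#' @export
coded_diagnosis <- function(system, code, position = 1L) {
  system <- match.arg(system, CODE_SYSTEMS)
  code <- normalize_code(code, system)
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stop("position must be a positive integer")
  structure(list(system = system, code = code, position = position),
            class = "coded_diagnosis")
}

#' Normalize and validate a code string for a coding system
#'
#' Uppercases and trims the code, then checks the system's syntax.  Codes
#' supplied without their decimal point (e.g. `"4109"`) are rejected rather
#' than guessed.
#'
#' @inheritParams coded_diagnosis
#' @return the normalized code string.
#' @export
normalize_code <- function(code, system) {
  system <- match.arg(system, CODE_SYSTEMS)
  code <- toupper(trimws(as.character(code)))
  if (length(code) != 1L || is.na(code) || !nzchar(code)) stop("code must be a non-empty string")
  pat <- switch(system,
    ICD9CM   = "^[0-9]{3}(\\.[0-9]{1,2})?$",
    IMO      = "^[0-9]{3}(\\.[0-9]{1,2})?[A-Z]*$",
    ICD9PROC = "^[0-9]{2}(\\.[0-9]{1,2})?$",
    CPT4     = "^[0-9]{5}$")
  if (!grepl(pat, code)) stop("malformed ", system, " code: '", code, "'")
  code
}

#' Create a laboratory result (troponin or BNP)
#'
#' Values are interpreted relative to `uln`, the assay's upper limit of
#' normal in the same units, so records from sites with different assays
#' remain comparable.
#'
#' @param analyte `"TROPONIN"` or `"BNP"`.
#' @param value measured concentration (assay units, non-negative).
#' @param uln assay upper limit of normal (same units, positive).
#' @param datetime collection time.
#' @return a `lab_result` object.
#' @export
lab_result <- function(analyte, value, uln, datetime) {
  analyte <- match.arg(analyte, c("TROPONIN", "BNP"))
  value <- as.numeric(value); uln <- as.numeric(uln)
  if (is.na(value) || value < 0) stop("lab value must be non-negative")
  if (is.na(uln) || uln <= 0) stop("uln must be positive")
  structure(list(analyte = analyte, value = value, uln = uln,
                 datetime = parse_datetime(datetime)),
            class = "lab_result")
}

#' Create an ECG record of coded interpretation statements
#'
#' `acronyms` are the numeric interpretation-statement codes stored by the
#' ECG database when a physician's text reading is encoded; codes 964-968
#' denote ST-segment elevation.
#'
#' @param datetime acquisition time.
#' @param acronyms integer vector of interpretation codes (may be empty).
#' @return an `ecg_record` object.
#' @export
ecg_record <- function(datetime, acronyms = integer()) {
  acronyms <- as.integer(acronyms)
  if (anyNA(acronyms) || any(acronyms < 0)) stop("acronyms must be non-negative integers")
  structure(list(datetime = parse_datetime(datetime), acronyms = acronyms),
            class = "ecg_record")
}

#' Create an echocardiogram record
#'
#' @param datetime study time.
#' @param ef_percent left-ventricular ejection fraction, percent in \[0, 100\].
#' @return an `echo_record` object.
#' @export
echo_record <- function(datetime, ef_percent) {
  ef_percent <- as.numeric(ef_percent)
  if (is.na(ef_percent) || ef_percent < 0 || ef_percent > 100)
    stop("ef_percent must lie in [0, 100]")
  structure(list(datetime = parse_datetime(datetime), ef_percent = ef_percent),
            class = "echo_record")
}

#' Create a hospitalization with its ordered discharge diagnosis list
#'
#' Diagnosis list order defines position: the first entry is the primary
#' discharge diagnosis.  Elective status is an input fact from the source
#' system, never inferred.
#'
#' @param admit,discharge admission and discharge timestamps (`admit <=
#'   discharge`).
#' @param elective logical; `TRUE` for an elective admission.
#' @param diagnoses list of [coded_diagnosis()] (systems ICD9CM/IMO); their
#'   `position` fields are (re)assigned 1..k from list order.
#' @param procedures list of [coded_diagnosis()] with system ICD9PROC or CPT4.
#' @return a `hospitalization` object.
#' @export
hospitalization <- function(admit, discharge, elective = FALSE,
                            diagnoses = list(), procedures = list()) {
  admit <- parse_datetime(admit); discharge <- parse_datetime(discharge)
  if (admit > discharge) stop("admit must not be after discharge")
  stopifnot(is.logical(elective), length(elective) == 1L, !is.na(elective))
  diagnoses <- check_dx_list(diagnoses, c("ICD9CM", "IMO"))
  for (i in seq_along(diagnoses)) diagnoses[[i]]$position <- i
  procedures <- check_dx_list(procedures, c("ICD9PROC", "CPT4"))
  structure(list(admit = admit, discharge = discharge, elective = elective,
                 diagnoses = diagnoses, procedures = procedures),
            class = "hospitalization")
}

check_dx_list <- function(x, systems) {
  if (!is.list(x)) stop("expected a list of coded_diagnosis")
  for (d in x) {
    if (!inherits(d, "coded_diagnosis")) stop("expected coded_diagnosis entries")
    if (!d$system %in% systems)
      stop("system ", d$system, " not allowed here (expected ",
           paste(systems, collapse = "/"), ")")
  }
  x
}

#' Create an insurance claim
#'
#' @param date service date.
#' @param place place of service: `"OFFICE"`, `"INPATIENT"`, `"ED"`, `"OTHER"`.
#' @param diagnoses non-empty list of [coded_diagnosis()].
#' @return a `claim` object.
#' @export
claim <- function(date, place, diagnoses) {
  place <- match.arg(place, CLAIM_PLACES)
  diagnoses <- check_dx_list(diagnoses, c("ICD9CM", "IMO"))
  if (length(diagnoses) == 0L) stop("claim must carry at least one diagnosis")
  structure(list(date = parse_datetime(date), place = place, diagnoses = diagnoses),
            class = "claim")
}

#' Assemble a patient's complete structured extract
#'
#' @param patient_id opaque identifier, unique within a cohort.
#' @param enrollment_start date enrollment (observation) began.
#' @param hospitalizations,labs,ecgs,echos,claims lists of the respective
#'   record types; all event timestamps must be on or after
#'   `enrollment_start`.
#' @return a `patient_record` object.
#' @export
patient_record <- function(patient_id, enrollment_start,
                           hospitalizations = list(), labs = list(),
                           ecgs = list(), echos = list(), claims = list()) {
  rec <- structure(list(patient_id = as.character(patient_id),
                        enrollment_start = parse_date(enrollment_start),
                        hospitalizations = hospitalizations, labs = labs,
                        ecgs = ecgs, echos = echos, claims = claims),
                   class = "patient_record")
  problems <- validate_patient_record(rec)
  if (length(problems)) stop("invalid patient record: ", paste(problems, collapse = "; "))
  rec
}

#' Validate a patient record, returning all problems found
#'
#' @param rec a `patient_record` (or candidate list).
#' @return character vector of problem descriptions; empty when valid.
#' @export
validate_patient_record <- function(rec) {
  p <- character()
  if (!is.list(rec)) return("record is not a list")
  if (is.null(rec$patient_id) || !nzchar(rec$patient_id)) p <- c(p, "missing patient_id")
  if (is.null(rec$enrollment_start) || anyNA(rec$enrollment_start))
    return(c(p, "missing enrollment_start"))
  e0 <- as.Date(rec$enrollment_start)
  chk <- function(items, cls, what, field = "datetime") {
    for (i in seq_along(items)) {
      it <- items[[i]]
      if (!inherits(it, cls)) { p <<- c(p, sprintf("%s %d is not a %s", what, i, cls)); next }
      ts <- if (cls == "hospitalization") it$admit else it[[field]]
      if (as.Date(ts) < e0)
        p <<- c(p, sprintf("%s %d predates enrollment_start", what, i))
    }
  }
  chk(rec$hospitalizations, "hospitalization", "hospitalization")
  chk(rec$labs, "lab_result", "lab")
  chk(rec$ecgs, "ecg_record", "ecg")
  chk(rec$echos, "echo_record", "echo")
  chk(rec$claims, "claim", "claim", field = "date")
  for (i in seq_along(rec$hospitalizations)) {
    h <- rec$hospitalizations[[i]]
    if (inherits(h, "hospitalization") && length(h$diagnoses)) {
      pos <- vapply(h$diagnoses, function(d) d$position, integer(1))
      if (!identical(pos, seq_along(pos)))
        p <- c(p, sprintf("hospitalization %d diagnosis positions are not 1..k", i))
    }
  }
  p
}

#' Define the period of interest for surveillance
#'
#' The calendar window over which events are classified (e.g. one calendar
#' year); hospitalizations are in scope when their discharge date falls
#' inside it.
#'
#' @param start,end dates with `start < end`.
#' @return a `period_of_interest` object.
#' @export
period_of_interest <- function(start, end) {
  start <- parse_date(start); end <- parse_date(end)
  if (!(start < end)) stop("period start must precede end")
  structure(list(start = start, end = end), class = "period_of_interest")
}

#' Link labs, ECGs and echos to hospital episodes of care
#'
#' Emits one episode per hospitalization whose discharge date falls inside
#' the period of interest.  An event is attached to an episode when its
#' timestamp lies in the window `[admit - 24 h, discharge + 24 h]`, so
#' pre-admission emergency-department troponins and discharge-day echos
#' travel with the stay; an event may attach to several overlapping
#' episodes.  Linkage is deterministic.
#'
#' @param record a [patient_record()].
#' @param period a [period_of_interest()].
#' @return list of `episode` objects (fields `hospitalization`, `labs`,
#'   `ecgs`, `echos`), ordered by admission time; empty list when no
#'   hospitalization qualifies.
#' @export
link_episodes <- function(record, period) {
  stopifnot(inherits(record, "patient_record"), inherits(period, "period_of_interest"))
  hosps <- record$hospitalizations
  if (length(hosps) == 0L) return(list())
  keep <- vapply(hosps, function(h) {
    d <- as.Date(h$discharge); d >= period$start && d <= period$end
  }, logical(1))
  hosps <- hosps[keep]
  if (length(hosps) == 0L) return(list())
  hosps <- hosps[order(vapply(hosps, function(h) as.numeric(h$admit), numeric(1)))]
  day <- 86400
  lapply(hosps, function(h) {
    lo <- h$admit - day; hi <- h$discharge + day
    pick <- function(items) {
      if (length(items) == 0L) return(list())
      items[vapply(items, function(it) it$datetime >= lo && it$datetime <= hi, logical(1))]
    }
    structure(list(hospitalization = h, labs = pick(record$labs),
                   ecgs = pick(record$ecgs), echos = pick(record$echos)),
              class = "episode")
  })
}

#' Years of observation accrued by a date
#'
#' Elapsed time from `enrollment_start` to `as_of` in 365.25-day years.
#' Comparison against the 2-year observation requirement is inclusive
#' (`>= 2`).
#'
#' @param record a [patient_record()].
#' @param as_of date at which observation is measured; must not precede
#'   enrollment.
#' @return non-negative number of years.
#' @export
observation_years <- function(record, as_of) {
  as_of <- parse_date(as_of)
  if (as_of < record$enrollment_start) stop("as_of precedes enrollment_start")
  as.numeric(as_of - record$enrollment_start) / 365.25
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s> enrolled %s: %d hospitalization(s), %d lab(s), %d ECG(s), %d echo(s), %d claim(s)\n",
              x$patient_id, format(x$enrollment_start),
              length(x$hospitalizations), length(x$labs), length(x$ecgs),
              length(x$echos), length(x$claims)))
  invisible(x)
}

#' @export
print.episode <- function(x, ...) {
  h <- x$hospitalization
  cat(sprintf("<episode> %s .. %s (%s): %d dx, %d lab(s), %d ECG(s), %d echo(s)\n",
              format(h$admit), format(h$discharge),
              if (h$elective) "elective" else "nonelective",
              length(h$diagnoses), length(x$labs), length(x$ecgs), length(x$echos)))
  invisible(x)
}
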
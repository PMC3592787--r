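# The three hierarchical event-classification algorithms.  Each version
# evaluates its category criteria against a patient's linked episodes of
# care and returns the highest-priority category satisfied; the hierarchy
# means, e.g., a STEMI complicated by acute heart failure is a STEMI.
#
# Inequalities are taken literally throughout: ">" strict for troponin and
# BNP relative to the assay ULN, "<=" inclusive for ejection fraction,
# ">=" inclusive for observation years.

VERSIONS <- c("V1", "V2", "V3")

#' Category hierarchy per algorithm version
#'
#' Categories in priority order (first = highest).  V1 merges STEMI and
#' nSTEMI into `MI_UNSPECIFIED` because ECG interpretation codes were not
#' searchable when that iteration ran; V3 drops unstable angina and merges
#' ambulatory presentation with chronic prevalent disease.
#'
#' @param version `"V1"`, `"V2"` or `"V3"`.
#' @return character vector of category labels, highest priority first
#'   (`UNCLASSIFIED` is the implicit fall-through and is not listed).
#' @export
version_categories <- function(version) {
  switch(match.arg(version, VERSIONS),
    V1 = c("MI_UNSPECIFIED", "SYSTOLIC_HF", "UNSTABLE_ANGINA", "AMBULATORY", "CHRONIC"),
    V2 = c("STEMI", "SYSTOLIC_HF", "NSTEMI", "UNSTABLE_ANGINA", "AMBULATORY", "CHRONIC"),
    V3 = c("STEMI", "SYSTOLIC_HF", "NSTEMI", "AMBULATORY_OR_CHRONIC"))
}

#' Configure the classification algorithm
#'
#' @param period the [period_of_interest()] over which events are classified.
#' @param ef_threshold ejection-fraction cutoff in percent; an EF at or
#'   below it denotes depressed systolic function (default 35).
#' @param min_observation_years observation required before a date for the
#'   ambulatory/chronic criteria (default 2; inclusive comparison).
#' @param st_elevation_acronyms inclusive integer range of ECG
#'   interpretation codes denoting ST elevation (default `c(964, 968)`).
#' @param troponin_multiplier_v1,troponin_multiplier_v23 troponin threshold
#'   as a multiple of the assay ULN: the first iteration used `> 1 x ULN`,
#'   the second and third `> 3 x ULN`.
#' @return an `algorithm_config` object.
#' @export
algorithm_config <- function(period,
                             ef_threshold = 35,
                             min_observation_years = 2,
                             st_elevation_acronyms = c(964L, 968L),
                             troponin_multiplier_v1 = 1,
                             troponin_multiplier_v23 = 3) {
  stopifnot(inherits(period, "period_of_interest"),
            ef_threshold > 0, min_observation_years >= 0,
            length(st_elevation_acronyms) == 2L,
            st_elevation_acronyms[1] <= st_elevation_acronyms[2],
            troponin_multiplier_v1 > 0, troponin_multiplier_v23 > 0)
  structure(list(period = period, ef_threshold = ef_threshold,
                 min_observation_years = min_observation_years,
                 st_elevation_acronyms = as.integer(st_elevation_acronyms),
                 troponin_multiplier_v1 = troponin_multiplier_v1,
                 troponin_multiplier_v23 = troponin_multiplier_v23),
            class = "algorithm_config")
}

troponin_multiplier <- function(config, version) {
  if (version == "V1") config$troponin_multiplier_v1 else config$troponin_multiplier_v23
}

#' Episode-level clinical predicates
#'
#' `troponin_exceeds()`: does any troponin linked to the episode exceed
#' `multiplier` times its assay ULN (strict `>`)?  `has_st_elevation()`:
#' does any linked ECG carry an interpretation code in the configured
#' ST-elevation range?  Both are vacuously `FALSE` when no such event is
#' linked.
#'
#' @param episode an episode from [link_episodes()].
#' @param multiplier positive troponin threshold multiple of ULN.
#' @param config an [algorithm_config()].
#' @return `TRUE`/`FALSE`.
#' @export
troponin_exceeds <- function(episode, multiplier) {
  stopifnot(multiplier > 0)
  for (lab in episode$labs)
    if (lab$analyte == "TROPONIN" && lab$value > multiplier * lab$uln) return(TRUE)
  FALSE
}

#' @rdname troponin_exceeds
#' @export
has_st_elevation <- function(episode, config) {
  rng <- config$st_elevation_acronyms
  for (ecg in episode$ecgs)
    if (any(ecg$acronyms >= rng[1] & ecg$acronyms <= rng[2])) return(TRUE)
  FALSE
}

bnp_above_uln <- function(episode) {
  for (lab in episode$labs)
    if (lab$analyte == "BNP" && lab$value > lab$uln) return(TRUE)
  FALSE
}

low_ef_on_echo <- function(episode, config) {
  for (echo in episode$echos)
    if (echo$ef_percent <= config$ef_threshold) return(TRUE)
  FALSE
}

#' Acute systolic heart-failure criterion for an episode
#'
#' Primary (position-1) discharge diagnosis of 425 or 428, plus at least
#' one linked BNP above its assay ULN, plus — for V2 and V3 — at least one
#' linked echocardiographic ejection fraction at or below the threshold.
#' The first iteration required only the code and the BNP.  A positive
#' troponin does not block this criterion (the MI categories sit above it
#' in the hierarchy).
#'
#' @param episode an episode from [link_episodes()].
#' @param version `"V1"`, `"V2"` or `"V3"`.
#' @param config an [algorithm_config()].
#' @return `TRUE`/`FALSE`.
#' @export
hf_criteria_met <- function(episode, version, config) {
  version <- match.arg(version, VERSIONS)
  sets <- codeset_cache()
  primary <- Filter(function(d) d$position == 1L, episode$hospitalization$diagnoses)
  if (!any_code_match(primary, sets$HF_CODES)) return(FALSE)
  if (!bnp_above_uln(episode)) return(FALSE)
  if (version != "V1" && !low_ef_on_echo(episode, config)) return(FALSE)
  TRUE
}

# One registry build per session: classification loops over cohorts should
# not rebuild spec lists per patient.
.cardioevent_env <- new.env(parent = emptyenv())
codeset_cache <- function() {
  if (is.null(.cardioevent_env$sets)) .cardioevent_env$sets <- builtin_codesets()
  .cardioevent_env$sets
}

# All (diagnosis, date) pairs across claims and hospitalizations; the
# hospitalization's admission date stands as the diagnosis date.
dated_diagnoses <- function(record) {
  out <- list()
  for (cl in record$claims)
    for (d in cl$diagnoses) out[[length(out) + 1L]] <- list(dx = d, date = cl$date)
  for (h in record$hospitalizations)
    for (d in h$diagnoses) out[[length(out) + 1L]] <- list(dx = d, date = h$admit)
  out
}

heart_disease_dates <- function(record, sets) {
  dd <- dated_diagnoses(record)
  dd <- Filter(function(e) code_matches_any(e$dx, sets$HEART_DISEASE), dd)
  if (length(dd) == 0L) return(NULL)
  sort(do.call(c, lapply(dd, function(e) e$date)))
}

code_matches_any <- function(dx, set) any_code_match(list(dx), set)

# >= min_observation_years accrued by `as_of`; FALSE (not an error) when
# enrollment began after `as_of`.
enough_observation <- function(record, as_of, config) {
  as_of <- parse_date(as_of)
  as_of >= record$enrollment_start &&
    observation_years(record, as_of) >= config$min_observation_years
}

hosp_has_code <- function(h, set) any_code_match(h$diagnoses, set)

in_period <- function(h, period) {
  d <- as.Date(h$discharge); d >= period$start && d <= period$end
}

#' Which category criteria does a record satisfy?
#'
#' Evaluates every category criterion of the given algorithm version
#' independently (no hierarchy), which makes the precedence rule itself
#' testable: [classify_patient()] returns the first satisfied category in
#' [version_categories()] order.
#'
#' @param record a [patient_record()].
#' @param version `"V1"`, `"V2"` or `"V3"`.
#' @param config an [algorithm_config()].
#' @return named logical vector over the version's categories, with a
#'   `"rationale"` attribute: a named list of the criterion identifiers
#'   that fired for each satisfied category.
#' @export
criteria_satisfied <- function(record, version, config) {
  version <- match.arg(version, VERSIONS)
  stopifnot(inherits(config, "algorithm_config"))
  problems <- validate_patient_record(record)
  if (length(problems)) stop("invalid patient record: ", paste(problems, collapse = "; "))
  sets <- codeset_cache()
  eps <- link_episodes(record, config$period)
  mult <- troponin_multiplier(config, version)
  cats <- version_categories(version)
  met <- stats::setNames(logical(length(cats)), cats)
  why <- stats::setNames(vector("list", length(cats)), cats)
  note <- function(cat, id) { met[[cat]] <<- TRUE; why[[cat]] <<- c(why[[cat]], id) }

  if (version == "V1") {
    ua_411 <- code_set("UA_411", px("411"))
    for (ep in eps) {
      dx <- ep$hospitalization$diagnoses
      if (troponin_exceeds(ep, mult)) {
        if (any_code_match(dx, sets$MI_ANY))
          note("MI_UNSPECIFIED", "discharge 410.0-410.9 + troponin > ULN")
        if (any_code_match(dx, sets$MI_AMBIGUOUS) ||
            any_code_match(dx, sets$OTHER_HEART_420_429))
          note("MI_UNSPECIFIED", "discharge 410.7-410.9/420-429 + troponin > ULN")
      }
      if (hf_criteria_met(ep, version, config))
        note("SYSTOLIC_HF", "primary 425/428 + BNP > ULN")
      # unstable angina, iteration 1: 411.x (only) and no troponin above ULN
      if (any_code_match(dx, ua_411) && !troponin_exceeds(ep, 1))
        note("UNSTABLE_ANGINA", "411.x + no troponin > ULN")
    }
    hd <- heart_disease_dates(record, sets)
    if (!is.null(hd)) {
      first_dx <- hd[1]
      enough_obs <- enough_observation(record, as.Date(first_dx), config)
      near_hosp <- any(vapply(record$hospitalizations, function(h) {
        !h$elective && abs(as.numeric(difftime(h$admit, first_dx, units = "days"))) <= 30
      }, logical(1)))
      if (enough_obs && !near_hosp)
        note("AMBULATORY", "no nonelective hospitalization within 30 d of first diagnosis + >= 2 y prior observation")
    }
    if (enough_observation(record, config$period$start, config)) {
      first_year_end <- record$enrollment_start + 365.25
      dd <- dated_diagnoses(record)
      chronic_early <- any(vapply(dd, function(e) {
        as.Date(e$date) <= first_year_end && code_matches_any(e$dx, sets$CHRONIC_V1)
      }, logical(1)))
      if (chronic_early)
        note("CHRONIC", "412-414/420-429 coded in first year of enrollment + >= 2 y observation")
    }
  }

  if (version == "V2") {
    for (ep in eps) {
      dx <- ep$hospitalization$diagnoses
      if (any_code_match(dx, sets$STEMI_ICD9_DEFINITE))
        note("STEMI", "discharge 410.0-410.6/410.8")
      if (any_code_match(dx, sets$MI_AMBIGUOUS) && has_st_elevation(ep, config) &&
          troponin_exceeds(ep, mult))
        note("STEMI", "410.7/410.9 + ST-elevation ECG code + troponin > 3 x ULN")
      if (hf_criteria_met(ep, version, config))
        note("SYSTOLIC_HF", "primary 425/428 + BNP > ULN + EF <= 35")
      if (any_code_match(dx, sets$MI_AMBIGUOUS) && !has_st_elevation(ep, config) &&
          troponin_exceeds(ep, mult))
        note("NSTEMI", "410.7/410.9 + no ST-elevation ECG code + troponin > 3 x ULN")
      if (any_code_match(dx, sets$UA_CODES) && !troponin_exceeds(ep, mult) &&
          !any_code_match(ep$hospitalization$procedures, sets$PACER_DEFIB))
        note("UNSTABLE_ANGINA", "411.x/786.5x + no troponin > 3 x ULN + no pacer/defibrillator procedure")
    }
    hd_claims <- Filter(function(cl) any_code_match(cl$diagnoses, sets$HEART_DISEASE),
                        record$claims)
    if (length(hd_claims)) {
      dates <- do.call(c, lapply(hd_claims, function(cl) cl$date))
      first <- hd_claims[[which.min(as.numeric(dates))]]
      if (first$place == "OFFICE" &&
          enough_observation(record, config$period$start, config))
        note("AMBULATORY", "first heart-disease claim from office + >= 2 y observation before period")
    }
    if (enough_observation(record, config$period$start, config)) {
      hd <- heart_disease_dates(record, sets)
      prior <- !is.null(hd) && as.Date(hd[1]) < config$period$start
      hd_hosp_in_period <- any(vapply(record$hospitalizations, function(h) {
        in_period(h, config$period) &&
          (hosp_has_code(h, sets$HEART_DISEASE) || hosp_has_code(h, sets$CHEST_PAIN))
      }, logical(1)))
      if (prior && !hd_hosp_in_period)
        note("CHRONIC", "heart disease before period + no heart-disease/chest-pain hospitalization in period + >= 2 y observation")
    }
  }

  if (version == "V3") {
    for (ep in eps) {
      dx <- ep$hospitalization$diagnoses
      if (any_code_match(dx, sets$STEMI_ICD9_DEFINITE))
        note("STEMI", "code starting 410.0-410.6/410.8")
      if (any_code_match(dx, sets$STEMI_IMO))
        note("STEMI", "STEMI-specific IMO term")
      if (any_code_match(dx, sets$NSTEMI_410_7))
        note("NSTEMI", "code starting 410.7")
      if (any_code_match(dx, sets$NSTEMI_IMO))
        note("NSTEMI", "nSTEMI-specific IMO term")
      if (hf_criteria_met(ep, version, config))
        note("SYSTOLIC_HF", "primary 425/428 + BNP > ULN + EF <= 35")
    }
    hd <- heart_disease_dates(record, sets)
    if (!is.null(hd)) {
      hd_hosp_in_period <- any(vapply(record$hospitalizations, function(h) {
        !h$elective && in_period(h, config$period) && hosp_has_code(h, sets$HEART_DISEASE)
      }, logical(1)))
      if (!hd_hosp_in_period)
        note("AMBULATORY_OR_CHRONIC", "heart-disease diagnosis + no nonelective heart-disease hospitalization in period")
    }
  }

  attr(met, "rationale") <- why[met]
  met
}

#' Classify one patient record
#'
#' Applies the version's category criteria and returns the
#' highest-priority satisfied category (`UNCLASSIFIED` when none holds).
#'
#' @inheritParams criteria_satisfied
#' @return an `event_class` object: list with `label`, `version`, and
#'   `rationale` (criterion identifiers that fired for the winning label).
#' @export
classify_patient <- function(record, version, config) {
  version <- match.arg(version, VERSIONS)
  met <- criteria_satisfied(record, version, config)
  why <- attr(met, "rationale")
  label <- "UNCLASSIFIED"; rationale <- character()
  for (cat in names(met)) {
    if (met[[cat]]) { label <- cat; rationale <- unique(why[[cat]]); break }
  }
  structure(list(label = label, version = version, rationale = rationale),
            class = "event_class")
}

#' @rdname classify_patient
#' @export
classify_v1 <- function(record, config) classify_patient(record, "V1", config)

#' @rdname classify_patient
#' @export
classify_v2 <- function(record, config) classify_patient(record, "V2", config)

#' @rdname classify_patient
#' @export
classify_v3 <- function(record, config) classify_patient(record, "V3", config)

#' @export
print.event_class <- function(x, ...) {
  cat(sprintf("<event_class %s> %s%s\n", x$version, x$label,
              if (length(x$rationale)) paste0(" [", paste(x$rationale, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Classify a cohort of patient records
#'
#' @param records list of [patient_record()] with unique `patient_id`s.
#' @param version `"V1"`, `"V2"` or `"V3"`.
#' @param config an [algorithm_config()].
#' @return a `cardio_classification` data frame with columns `patient_id`,
#'   `version`, `label`, `rationale` (criterion ids joined by `"; "`).
#' @export
classify_cohort <- function(records, version, config) {
  version <- match.arg(version, VERSIONS)
  ids <- vapply(records, function(r) r$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient_id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(records, function(r) {
    cls <- classify_patient(r, version, config)
    data.frame(patient_id = r$patient_id, version = version, label = cls$label,
               rationale = paste(cls$rationale, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), version = character(),
               label = character(), rationale = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("cardio_classification", "data.frame")
  out
}

#' @export
print.cardio_classification <- function(x, ...) {
  cat(sprintf("Event classification (%s), %d patient(s)\n",
              if (nrow(x)) x$version[1] else "-", nrow(x)))
  if (nrow(x)) print(table(label = x$label))
  invisible(x)
}

#' @export
summary.cardio_classification <- function(object, ...) {
  tab <- table(factor(object$label))
  structure(list(n = nrow(object),
                 version = if (nrow(object)) object$version[1] else NA_character_,
                 counts = tab), class = "summary.cardio_classification")
}

#' @export
print.summary.cardio_classification <- function(x, ...) {
  cat(sprintf("Cohort of %d patient(s), algorithm %s\n", x$n, x$version))
  print(x$counts)
  invisible(x)
}
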
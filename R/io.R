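# File interfaces: JSON-lines cohorts (one patient object per line, so
# extracts stream and diff cleanly), classification CSVs, gold-label CSVs,
# agreement-report JSON, YAML configuration, and the run manifest.

fmt_dt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

record_to_list <- function(rec) {
  dxl <- function(ds) lapply(ds, function(d) list(system = d$system, code = d$code))
  list(
    patient_id = rec$patient_id,
    enrollment_start = format(rec$enrollment_start),
    hospitalizations = lapply(rec$hospitalizations, function(h) list(
      admit = fmt_dt(h$admit), discharge = fmt_dt(h$discharge),
      elective = h$elective, diagnoses = dxl(h$diagnoses),
      procedures = dxl(h$procedures))),
    labs = lapply(rec$labs, function(l) list(
      analyte = l$analyte, value = l$value, uln = l$uln,
      datetime = fmt_dt(l$datetime))),
    ecgs = lapply(rec$ecgs, function(e) list(
      datetime = fmt_dt(e$datetime), acronyms = as.integer(e$acronyms))),
    echos = lapply(rec$echos, function(e) list(
      datetime = fmt_dt(e$datetime), ef_percent = e$ef_percent)),
    claims = lapply(rec$claims, function(cl) list(
      date = fmt_dt(cl$date), place = cl$place, diagnoses = dxl(cl$diagnoses)))
  )
}

list_to_record <- function(obj) {
  need <- function(x, field) {
    if (is.null(x[[field]])) stop("missing field '", field, "'")
    x[[field]]
  }
  dxl <- function(ds, pos = TRUE) {
    out <- lapply(seq_along(ds), function(i)
      coded_diagnosis(need(ds[[i]], "system"), need(ds[[i]], "code"),
                      position = if (pos) i else 1L))
    out
  }
  patient_record(
    patient_id = need(obj, "patient_id"),
    enrollment_start = need(obj, "enrollment_start"),
    hospitalizations = lapply(obj$hospitalizations, function(h)
      hospitalization(need(h, "admit"), need(h, "discharge"),
                      elective = isTRUE(h$elective),
                      diagnoses = dxl(h$diagnoses),
                      procedures = dxl(h$procedures, pos = FALSE))),
    labs = lapply(obj$labs, function(l)
      lab_result(need(l, "analyte"), need(l, "value"), need(l, "uln"),
                 need(l, "datetime"))),
    ecgs = lapply(obj$ecgs, function(e)
      ecg_record(need(e, "datetime"),
                 acronyms = as.integer(unlist(e$acronyms)))),
    echos = lapply(obj$echos, function(e)
      echo_record(need(e, "datetime"), need(e, "ef_percent"))),
    claims = lapply(obj$claims, function(cl)
      claim(need(cl, "date"), need(cl, "place"), diagnoses = dxl(cl$diagnoses)))
  )
}

#' Read a cohort from a JSON-lines file
#'
#' One patient object per line (see the package README for the schema).
#' Blank lines are ignored.  Malformed lines are all reported together,
#' each with its line number, before the function stops.
#'
#' @param path JSON-lines file.
#' @return list of [patient_record()] objects (empty, with a warning, for
#'   an empty file).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    warning("empty cohort file: ", path)
    return(list())
  }
  records <- vector("list", length(keep))
  errors <- character()
  for (j in seq_along(keep)) {
    ln <- keep[j]
    records[[j]] <- tryCatch({
      obj <- jsonlite::fromJSON(lines[ln], simplifyVector = FALSE)
      list_to_record(obj)
    }, error = function(e) {
      errors <<- c(errors, sprintf("line %d: %s", ln, conditionMessage(e)))
      NULL
    })
  }
  if (length(errors))
    stop("malformed cohort records:\n  ", paste(errors, collapse = "\n  "))
  records
}

#' Write a cohort as JSON-lines
#'
#' @param records list of [patient_record()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE,
                                  digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write classification tables
#'
#' CSV with columns `patient_id,version,label,rationale`; rationale strings
#' containing commas are quoted.  Files are UTF-8, newline-terminated, with
#' stable column order.
#'
#' @param table a `cardio_classification` data frame.
#' @param path CSV file.
#' @return [write_classifications()] returns `path` invisibly;
#'   [read_classifications()] returns a `cardio_classification` data frame.
#' @export
write_classifications <- function(table, path) {
  cols <- c("patient_id", "version", "label", "rationale")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classifications
#' @export
read_classifications <- function(path) {
  out <- utils::read.csv(path, colClasses = "character")
  class(out) <- c("cardio_classification", "data.frame")
  out
}

#' Read / write gold-standard labels
#'
#' CSV with columns `patient_id,label` (the manual chart-review result).
#'
#' @param labels data frame with `patient_id` and `label`, or a named
#'   character vector.
#' @param path CSV file.
#' @return [read_gold_labels()] returns a named character vector
#'   (names = patient ids).
#' @export
read_gold_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("patient_id", "label") %in% names(df)))
    stop("gold CSV needs columns patient_id,label")
  stats::setNames(df$label, df$patient_id)
}

#' @rdname read_gold_labels
#' @export
write_gold_labels <- function(labels, path) {
  if (!is.data.frame(labels))
    labels <- data.frame(patient_id = names(labels), label = unname(labels),
                         stringsAsFactors = FALSE)
  utils::write.csv(labels[, c("patient_id", "label")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write an agreement report as JSON
#'
#' Serialization is lossless at full double precision: reading a written
#' report reproduces every statistic exactly.  The confusion matrix is
#' embedded row-wise under `confusion`.
#'
#' @param report an `agreement_report` from [validation_report()].
#' @param path JSON file.
#' @return [read_report()] returns an `agreement_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  out <- list(
    n = report$n,
    observed_agreement = report$observed_agreement,
    kappa = report$kappa,
    ci_low = report$ci_low,
    ci_high = report$ci_high,
    level = report$level,
    labels = report$matrix$labels,
    confusion = apply(report$matrix$counts, 1, as.integer, simplify = FALSE),
    per_category = report$per_category
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  labels <- as.character(x$labels)
  counts <- do.call(rbind, lapply(x$confusion, as.integer))
  dimnames(counts) <- list(algorithm = labels, gold = labels)
  m <- confusion_from_counts(counts, labels)
  structure(list(matrix = m, n = as.integer(x$n),
                 observed_agreement = x$observed_agreement,
                 per_category = as.data.frame(x$per_category),
                 kappa = x$kappa, ci_low = x$ci_low, ci_high = x$ci_high,
                 level = x$level),
            class = "agreement_report")
}

#' Read an algorithm configuration from YAML
#'
#' Keys: `version` (1/2/3 or "V1".."V3"), `period: {start, end}`, and the
#' optional threshold overrides `ef_threshold`, `min_observation_years`,
#' `st_elevation_acronyms` (pair), `troponin_multiplier` (overrides the
#' version's default).
#'
#' @param path YAML file.
#' @return list with `version` and `config` (an [algorithm_config()]).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$period$start) || is.null(y$period$end))
    stop("config must give period: {start, end}")
  version <- toupper(as.character(y$version %||% "3"))
  if (!startsWith(version, "V")) version <- paste0("V", version)
  version <- match.arg(version, VERSIONS)
  args <- list(period = period_of_interest(y$period$start, y$period$end))
  for (k in c("ef_threshold", "min_observation_years"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$st_elevation_acronyms))
    args$st_elevation_acronyms <- as.integer(unlist(y$st_elevation_acronyms))
  if (!is.null(y$troponin_multiplier)) {
    if (version == "V1") args$troponin_multiplier_v1 <- y$troponin_multiplier
    else args$troponin_multiplier_v23 <- y$troponin_multiplier
  }
  list(version = version, config = do.call(algorithm_config, args))
}

#' Build a reproducibility manifest for a run
#'
#' Captures the package version, MD5 digests of the input files and of the
#' effective configuration, the seed (if any), and a timestamp.  Reruns on
#' identical inputs yield identical digests.
#'
#' @param inputs character vector of input file paths.
#' @param config any serializable configuration object (digested via its
#'   canonical JSON form).
#' @param seed integer seed used, or `NULL`.
#' @return a `run_manifest` list.
#' @export
run_manifest <- function(inputs = character(), config = NULL, seed = NULL) {
  digest_obj <- function(obj) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = NA, force = TRUE)), f)
    unname(tools::md5sum(f))
  }
  file_digests <- if (length(inputs))
    stats::setNames(unname(tools::md5sum(inputs)), basename(inputs))
  else NULL
  structure(list(
    tool = "cardioevent",
    version = as.character(utils::packageVersion("cardioevent")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = seed,
    config_digest = if (!is.null(config)) digest_obj(config) else NULL,
    input_digests = file_digests
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
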
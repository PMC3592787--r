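# Declarative code matching for ICD-9-CM ranges, IMO interface-terminology
# term lists, and procedure-code exclusions.  Four spec kinds cover every
# rule the classifiers need: EXACT, PREFIX (code-boundary aware), RUBRIC_RANGE
# (numeric on the decimal code string, so "410.10" < "410.9" behaves
# correctly), and PREFIX_EXCEPT (a prefix minus listed codes, e.g. 410.91
# except 410.91D).

#' Create a code-matching rule
#'
#' @param system coding system the rule applies to; a code from any other
#'   system never matches (mixed-vocabulary extracts are expected, so a
#'   mismatch is `FALSE`, not an error).
#' @param kind `"EXACT"`, `"PREFIX"`, `"RUBRIC_RANGE"`, or `"PREFIX_EXCEPT"`.
#' @param payload the code (EXACT) or prefix (PREFIX, PREFIX_EXCEPT).
#' @param low,high inclusive rubric endpoints for RUBRIC_RANGE, e.g.
#'   `"420"`/`"429"` or `"37.80"`/`"37.99"`; both endpoints must carry the
#'   same number of decimal digits.
#' @param except non-empty character vector of excluded codes for
#'   PREFIX_EXCEPT.
#' @return a `code_spec` object.
#' @export
code_spec <- function(system, kind, payload = NULL, low = NULL, high = NULL,
                      except = NULL) {
  system <- match.arg(system, CODE_SYSTEMS)
  kind <- match.arg(kind, c("EXACT", "PREFIX", "RUBRIC_RANGE", "PREFIX_EXCEPT"))
  if (kind == "RUBRIC_RANGE") {
    if (is.null(low) || is.null(high)) stop("RUBRIC_RANGE needs low and high")
    low <- toupper(trimws(low)); high <- toupper(trimws(high))
    if (n_decimals(low) != n_decimals(high))
      stop("range endpoints must share decimal granularity")
    if (rubric_key(low, n_decimals(low)) > rubric_key(high, n_decimals(high)))
      stop("range low must not exceed high")
  } else {
    if (is.null(payload) || !nzchar(trimws(payload))) stop("malformed spec: empty payload")
    payload <- toupper(trimws(payload))
  }
  if (kind == "PREFIX_EXCEPT") {
    if (is.null(except) || length(except) == 0L) stop("PREFIX_EXCEPT needs exclusions")
    except <- toupper(trimws(except))
  }
  structure(list(system = system, kind = kind, payload = payload,
                 low = low, high = high, except = except),
            class = "code_spec")
}

n_decimals <- function(x) {
  if (!grepl(".", x, fixed = TRUE)) return(0L)
  nchar(sub("^[^.]*\\.", "", x))
}

# Numeric key of a code's rubric truncated/zero-padded to `digits` decimal
# places; letters (IMO suffixes) are ignored.  NA when the code has no
# digits at all.
rubric_key <- function(code, digits) {
  num <- sub("^([0-9]+(\\.[0-9]+)?).*$", "\\1", code)
  if (!grepl("^[0-9]", num)) return(NA_real_)
  parts <- strsplit(num, ".", fixed = TRUE)[[1]]
  int <- as.numeric(parts[1])
  dec <- if (length(parts) > 1L) parts[2] else ""
  dec <- substr(paste0(dec, strrep("0", digits)), 1L, digits)
  int * 10^digits + if (digits > 0L) as.numeric(paste0("0", dec)) else 0
}

# Does `code` start with `prefix` at a code boundary?  The remainder after
# the prefix must be further digits (optionally, for IMO, trailing letters);
# when the prefix has no decimal point the remainder must open the decimal
# part ("425" matches "425" and "425.4", never "4254").
prefix_match <- function(code, prefix, system) {
  if (code == prefix) return(TRUE)
  if (!startsWith(code, prefix)) return(FALSE)
  rest <- substring(code, nchar(prefix) + 1L)
  if (grepl(".", prefix, fixed = TRUE)) {
    pat <- if (system == "IMO") "^[0-9]*[A-Z]*$" else "^[0-9]+$"
  } else {
    pat <- if (system == "IMO") "^\\.[0-9]+[A-Z]*$" else "^\\.[0-9]+$"
  }
  grepl(pat, rest)
}

#' Test one coded diagnosis against one code rule
#'
#' @param code a [coded_diagnosis()].
#' @param spec a [code_spec()].
#' @return `TRUE`/`FALSE`; `FALSE` whenever the systems disagree.
#' @export
code_matches <- function(code, spec) {
  stopifnot(inherits(code, "coded_diagnosis"), inherits(spec, "code_spec"))
  if (code$system != spec$system) return(FALSE)
  switch(spec$kind,
    EXACT = identical(code$code, spec$payload),
    PREFIX = prefix_match(code$code, spec$payload, code$system),
    RUBRIC_RANGE = {
      d <- n_decimals(spec$low)
      key <- rubric_key(code$code, d)
      !is.na(key) && key >= rubric_key(spec$low, d) && key <= rubric_key(spec$high, d)
    },
    PREFIX_EXCEPT = prefix_match(code$code, spec$payload, code$system) &&
      !(code$code %in% spec$except))
}

#' Create a named set of code rules
#'
#' @param name set name (unique within a registry).
#' @param specs list of [code_spec()] rules; a code is in the set when any
#'   rule matches.
#' @return a `code_set` object.
#' @export
code_set <- function(name, specs) {
  stopifnot(is.character(name), nzchar(name), is.list(specs))
  for (s in specs) if (!inherits(s, "code_spec")) stop("specs must be code_spec objects")
  structure(list(name = name, specs = specs), class = "code_set")
}

#' Does any diagnosis in a list fall in a code set?
#'
#' @param codes list of [coded_diagnosis()] (may be empty).
#' @param set a [code_set()].
#' @return `TRUE` iff some (code, rule) pair matches.
#' @export
any_code_match <- function(codes, set) {
  stopifnot(inherits(set, "code_set"))
  for (code in codes) for (spec in set$specs)
    if (code_matches(code, spec)) return(TRUE)
  FALSE
}

# Expand one prefix rule across diagnosis vocabularies: IMO terms are
# ICD-9-CM-rooted, so "any code starting with 410.7" is read in both.
px <- function(payload, systems = c("ICD9CM", "IMO")) {
  lapply(systems, code_spec, kind = "PREFIX", payload = payload)
}
rr <- function(low, high, systems = c("ICD9CM", "IMO")) {
  lapply(systems, code_spec, kind = "RUBRIC_RANGE", low = low, high = high)
}
im_exact <- function(codes) lapply(codes, function(cd) code_spec("IMO", "EXACT", cd))

#' Built-in diagnosis and procedure code sets
#'
#' The named code sets used by the three classification algorithm versions:
#'
#' * `HEART_DISEASE` — rubrics 410-414 plus 425 and 428 (the footnote-e
#'   heart-disease definition used for ambulatory/chronic criteria).
#' * `STEMI_ICD9_DEFINITE` — codes starting with 410.0-410.6 or 410.8.
#' * `MI_AMBIGUOUS` — 410.7 and 410.9 (STEMI vs nSTEMI not resolvable at
#'   4-digit ICD-9-CM granularity).
#' * `MI_ANY` — all of 410.
#' * `STEMI_IMO` / `NSTEMI_IMO` — the IMO interface-terminology term lists
#'   that split 410.9 into STEMI and nSTEMI (410.91 counts as nSTEMI except
#'   410.91D, which is STEMI-specific).
#' * `NSTEMI_410_7` — codes starting with 410.7.
#' * `HF_CODES` — 425 and 428.
#' * `OTHER_HEART_420_429`, `CHRONIC_V1` (412-414 and 420-429),
#'   `UA_CODES` (411.x, 786.5x), `CHEST_PAIN` (786.5),
#' * `PACER_DEFIB` — pacemaker/defibrillator insertion or revision
#'   procedures (ICD-9 procedures 37.80-37.99; CPT-4 33216).
#'
#' @return named list of [code_set()] objects.
#' @export
builtin_codesets <- function() {
  stemi_imo <- c("410.90CP", "410.90CS", "410.90CU", "410.90CX", "410.90DV",
                 "410.90FZ", "410.90GB", "410.90GD", "410.91D", "410.92F",
                 "410.92S")
  nstemi_imo <- c("410.90BT", "410.90CQ", "410.90CR", "410.90FY", "410.90GC",
                  "410.90GE", "410.90N", "410.92E", "410.92H")
  sets <- list(
    code_set("HEART_DISEASE", c(rr("410", "414"), px("425"), px("428"))),
    code_set("STEMI_ICD9_DEFINITE",
             do.call(c, lapply(c("410.0", "410.1", "410.2", "410.3", "410.4",
                                 "410.5", "410.6", "410.8"), px))),
    code_set("MI_AMBIGUOUS", c(px("410.7"), px("410.9"))),
    code_set("MI_ANY", px("410")),
    code_set("STEMI_IMO", im_exact(stemi_imo)),
    code_set("NSTEMI_IMO",
             c(im_exact(nstemi_imo),
               list(code_spec("IMO", "PREFIX_EXCEPT", payload = "410.91",
                              except = "410.91D")))),
    code_set("NSTEMI_410_7", px("410.7")),
    code_set("HF_CODES", c(px("425"), px("428"))),
    code_set("OTHER_HEART_420_429", rr("420", "429")),
    code_set("UA_CODES", c(px("411"), px("786.5"))),
    code_set("CHEST_PAIN", px("786.5")),
    code_set("PACER_DEFIB",
             list(code_spec("ICD9PROC", "RUBRIC_RANGE", low = "37.80", high = "37.99"),
                  code_spec("CPT4", "EXACT", payload = "33216"))),
    code_set("CHRONIC_V1", c(rr("412", "414"), rr("420", "429")))
  )
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Load additional code sets from a YAML file
#'
#' Sites can extend or override term lists (the published IMO nSTEMI list is
#' explicitly non-exhaustive) without code changes.  Layout:
#' ```yaml
#' MY_SET:
#'   - {system: IMO, kind: EXACT, payload: "410.92X"}
#'   - {system: ICD9CM, kind: RUBRIC_RANGE, low: "420", high: "429"}
#'   - {system: IMO, kind: PREFIX_EXCEPT, payload: "410.91", except: ["410.91D"]}
#' ```
#'
#' @param path YAML file of `name -> list of rules`.
#' @param base registry to extend (default [builtin_codesets()]); same-name
#'   sets are replaced.
#' @return named list of [code_set()] objects.
#' @export
read_codesets_yaml <- function(path, base = builtin_codesets()) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("codesets YAML must map names to rule lists")
  for (nm in names(raw)) {
    specs <- lapply(raw[[nm]], function(r) {
      code_spec(system = r$system, kind = r$kind, payload = r$payload,
                low = r$low, high = r$high, except = unlist(r$except))
    })
    base[[nm]] <- code_set(nm, specs)
  }
  base
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf("<code_set %s> %d rule(s)\n", x$name, length(x$specs)))
  for (s in x$specs) {
    desc <- switch(s$kind,
      EXACT = s$payload,
      PREFIX = paste0(s$payload, "*"),
      RUBRIC_RANGE = paste0("[", s$low, "-", s$high, "]"),
      PREFIX_EXCEPT = paste0(s$payload, "* except ", paste(s$except, collapse = ",")))
    cat(sprintf("  %-8s %-13s %s\n", s$system, s$kind, desc))
  }
  invisible(x)
}
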
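# The built-in sets are checked against an independent enumeration oracle
# (helper-oracles.R): membership is restated there from rubric arithmetic
# alone, with no reference to the spec kinds the implementation uses.

test_that("built-in sets agree with the enumeration oracle on the ICD-9 space", {
  sets <- builtin_codesets()
  codes <- icd9_universe()
  for (nm in names(codeset_oracle)) {
    got <- vapply(codes, function(cd)
      any_code_match(list(coded_diagnosis("ICD9CM", cd)), sets[[nm]]), logical(1))
    want <- vapply(codes, function(cd) codeset_oracle[[nm]](int_part(cd), first_dec(cd)),
                   logical(1))
    expect_identical(unname(got), unname(want), label = nm)
  }
})

test_that("prefix matching respects code boundaries and system gating", {
  p4107 <- code_spec("ICD9CM", "PREFIX", "410.7")
  expect_true(code_matches(coded_diagnosis("ICD9CM", "410.71"), p4107))
  expect_true(code_matches(coded_diagnosis("ICD9CM", "410.70"), p4107))
  expect_true(code_matches(coded_diagnosis("ICD9CM", "410.7"), p4107))
  expect_false(code_matches(coded_diagnosis("ICD9CM", "410.9"), p4107))
  # undotted prefixes stop at the decimal boundary
  p425 <- code_spec("ICD9CM", "PREFIX", "425")
  expect_true(code_matches(coded_diagnosis("ICD9CM", "425"), p425))
  expect_true(code_matches(coded_diagnosis("ICD9CM", "425.4"), p425))
  expect_true(code_matches(coded_diagnosis("ICD9CM", "786.50"),
                           code_spec("ICD9CM", "PREFIX", "786.5")))
  # an IMO code never matches an ICD9CM rule, and vice versa
  expect_false(code_matches(coded_diagnosis("IMO", "410.71X"), p4107))
  expect_true(code_matches(coded_diagnosis("IMO", "410.71X"),
                           code_spec("IMO", "PREFIX", "410.7")))
  expect_error(code_spec("ICD9CM", "PREFIX", ""), "empty payload")
})

test_that("rubric ranges compare numerically, not lexicographically", {
  r <- code_spec("ICD9CM", "RUBRIC_RANGE", low = "420", high = "429")
  expect_false(code_matches(coded_diagnosis("ICD9CM", "412.0"), r))
  expect_true(code_matches(coded_diagnosis("ICD9CM", "425.4"), r))
  # "410.10" sorts below "410.9" numerically although not lexicographically
  r2 <- code_spec("ICD9CM", "RUBRIC_RANGE", low = "410.0", high = "410.6")
  expect_true(code_matches(coded_diagnosis("ICD9CM", "410.10"), r2))
  expect_false(code_matches(coded_diagnosis("ICD9CM", "410.9"), r2))
  expect_error(code_spec("ICD9CM", "RUBRIC_RANGE", low = "429", high = "420"),
               "low must not exceed")
})

test_that("IMO term lists behave per the third-iteration coding rules", {
  sets <- builtin_codesets()
  imo <- function(cd) list(coded_diagnosis("IMO", cd))
  expect_true(any_code_match(imo("410.90CP"), sets$STEMI_IMO))
  expect_true(any_code_match(imo("410.91D"), sets$STEMI_IMO))
  expect_false(any_code_match(imo("410.91D"), sets$NSTEMI_IMO))  # the one exception
  expect_true(any_code_match(imo("410.91B"), sets$NSTEMI_IMO))
  expect_true(any_code_match(imo("410.91"), sets$NSTEMI_IMO))
  # bare 410.92 with no letter suffix belongs to neither list
  expect_false(any_code_match(imo("410.92"), sets$STEMI_IMO))
  expect_false(any_code_match(imo("410.92"), sets$NSTEMI_IMO))

  # disjointness over a broad IMO code space
  stemi_terms <- c("410.90CP", "410.90CS", "410.90CU", "410.90CX", "410.90DV",
                   "410.90FZ", "410.90GB", "410.90GD", "410.91D", "410.92F",
                   "410.92S")
  nstemi_terms <- c("410.90BT", "410.90CQ", "410.90CR", "410.90FY", "410.90GC",
                    "410.90GE", "410.90N", "410.92E", "410.92H", "410.91B")
  space <- c(stemi_terms, nstemi_terms, "410.90", "410.91", "410.92",
             "410.91DA", "410.92ZZ", "410.90Z")
  both <- vapply(space, function(cd)
    any_code_match(imo(cd), sets$STEMI_IMO) &&
      any_code_match(imo(cd), sets$NSTEMI_IMO), logical(1))
  expect_false(any(both))
})

test_that("MI_ANY contains the union of definite-STEMI and ambiguous codes", {
  sets <- builtin_codesets()
  for (cd in icd9_universe()) {
    dx <- list(coded_diagnosis("ICD9CM", cd))
    in_sub <- any_code_match(dx, sets$STEMI_ICD9_DEFINITE) ||
      any_code_match(dx, sets$MI_AMBIGUOUS)
    if (in_sub) expect_true(any_code_match(dx, sets$MI_ANY), label = cd)
  }
  expect_false(any_code_match(list(coded_diagnosis("ICD9CM", "410.9")),
                              sets$STEMI_ICD9_DEFINITE))
})

test_that("procedure set covers ICD-9 37.80-37.99 and CPT-4 33216", {
  sets <- builtin_codesets()
  expect_true(any_code_match(list(coded_diagnosis("ICD9PROC", "37.85")),
                             sets$PACER_DEFIB))
  expect_true(any_code_match(list(coded_diagnosis("ICD9PROC", "37.99")),
                             sets$PACER_DEFIB))
  expect_false(any_code_match(list(coded_diagnosis("ICD9PROC", "37.79")),
                              sets$PACER_DEFIB))
  expect_true(any_code_match(list(coded_diagnosis("CPT4", "33216")),
                             sets$PACER_DEFIB))
  expect_false(any_code_match(list(coded_diagnosis("CPT4", "33217")),
                              sets$PACER_DEFIB))
  expect_false(any_code_match(list(), sets$PACER_DEFIB))
})

test_that("YAML registry extension adds and overrides sets", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "SITE_NSTEMI:",
    "  - {system: IMO, kind: EXACT, payload: '410.92X'}",
    "  - {system: IMO, kind: PREFIX_EXCEPT, payload: '410.91', except: ['410.91D']}"
  ), f)
  reg <- read_codesets_yaml(f)
  expect_true("SITE_NSTEMI" %in% names(reg))
  expect_true(any_code_match(list(coded_diagnosis("IMO", "410.92X")),
                             reg$SITE_NSTEMI))
  expect_false(any_code_match(list(coded_diagnosis("IMO", "410.91D")),
                              reg$SITE_NSTEMI))
  expect_true("HEART_DISEASE" %in% names(reg))  # builtins retained
})
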
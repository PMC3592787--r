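test_that("generated records classify to their gold label for every category x version", {
  combos <- all_category_versions()
  for (i in seq_len(nrow(combos))) {
    v <- combos$version[i]; cat <- combos$category[i]
    for (seed in 1:25) {
      g <- generate_patient(cat, v, TEST_CONFIG, seed = 1000 * i + seed)
      expect_identical(g$gold, cat)
      expect_equal(label_of(g$record, v), cat,
                   label = sprintf("%s %s seed %d", v, cat, seed))
    }
  }
})

test_that("invalid category/version pairs are rejected", {
  expect_error(generate_patient("UNSTABLE_ANGINA", "V3", TEST_CONFIG, seed = 1),
               "not valid for V3")
  expect_error(generate_patient("STEMI", "V1", TEST_CONFIG, seed = 1),
               "not valid for V1")
  expect_error(cohort_spec("V3", counts = c(UNSTABLE_ANGINA = 3), seed = 1),
               "valid for V3")
  expect_error(cohort_spec("V3", counts = c(STEMI = 3)), "seed")
  expect_error(cohort_spec("V3", counts = c(STEMI = 3), seed = 1,
                           discordance = data.frame(algorithm = "STEMI",
                                                    gold = "STEMI", count = 1)),
               "distinct")
})

test_that("cohort generation is deterministic and insertion-order stable", {
  spec <- cohort_spec("V2", counts = c(STEMI = 4, NSTEMI = 4, SYSTOLIC_HF = 3),
                      seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort(c1$records, f1); write_cohort(c2$records, f2)
  expect_identical(readLines(f1), readLines(f2))

  # adding a category at the end leaves earlier patients' data untouched
  spec_more <- cohort_spec("V2", counts = c(STEMI = 4, NSTEMI = 4,
                                            SYSTOLIC_HF = 3, CHRONIC = 2),
                           seed = 11)
  c3 <- generate_cohort(spec_more)
  expect_identical(c1$records, c3$records[seq_along(c1$records)])
})

test_that("requested discordance equals realized discordance exactly", {
  disc <- data.frame(algorithm = c("STEMI", "NSTEMI"),
                     gold = c("SYSTOLIC_HF", "SYSTOLIC_HF"),
                     count = c(2L, 1L))
  spec <- cohort_spec("V3",
                      counts = c(STEMI = 5, NSTEMI = 5, SYSTOLIC_HF = 5,
                                 AMBULATORY_OR_CHRONIC = 5),
                      discordance = disc, seed = 23)
  coh <- generate_cohort(spec)
  tab <- classify_cohort(coh$records, "V3", coh$config)
  labels <- c(version_categories("V3"), "UNCLASSIFIED")
  m <- confusion_matrix(setNames(tab$label, tab$patient_id),
                        setNames(coh$gold$label, coh$gold$patient_id), labels)
  expect_equal(m$counts["STEMI", "SYSTOLIC_HF"], 2)
  expect_equal(m$counts["NSTEMI", "SYSTOLIC_HF"], 1)
  expect_equal(sum(m$counts) - sum(diag(m$counts)), 3)  # nothing else off-diagonal
  expect_equal(unname(diag(m$counts)[labels != "UNCLASSIFIED"][1:4]), c(5, 5, 5, 5))
})

test_that("zero discordance gives perfect agreement; infeasible pairs error", {
  spec <- cohort_spec("V3", counts = c(STEMI = 3, SYSTOLIC_HF = 3), seed = 5)
  coh <- generate_cohort(spec)
  tab <- classify_cohort(coh$records, "V3", coh$config)
  rep <- validation_report(setNames(tab$label, tab$patient_id),
                           setNames(coh$gold$label, coh$gold$patient_id),
                           c("STEMI", "SYSTOLIC_HF"))
  expect_equal(rep$kappa, 1)

  bad <- cohort_spec("V3", counts = c(STEMI = 1),
                     discordance = data.frame(algorithm = "AMBULATORY_OR_CHRONIC",
                                              gold = "STEMI", count = 1),
                     seed = 2)
  expect_error(generate_cohort(bad), "infeasible")
})

test_that("the canonical discordant record is an HF admission coded as nSTEMI", {
  for (v in c("V2", "V3")) {
    spec <- cohort_spec(v,
                        counts = setNames(1L, "SYSTOLIC_HF"),
                        discordance = data.frame(algorithm = "NSTEMI",
                                                 gold = "SYSTOLIC_HF", count = 1L),
                        seed = 31)
    coh <- generate_cohort(spec)
    disc_rec <- coh$records[[2]]
    expect_equal(label_of(disc_rec, v), "NSTEMI")
    # the clinical heart-failure evidence is present on the record
    ep <- link_episodes(disc_rec, TEST_PERIOD)[[1]]
    codes <- vapply(ep$hospitalization$diagnoses, function(d) d$code, character(1))
    expect_true("428.0" %in% codes)
    expect_true(any(vapply(ep$labs, function(l) l$analyte == "BNP" &&
                             l$value > l$uln, logical(1))))
    expect_true(any(vapply(ep$echos, function(e) e$ef_percent <= 35, logical(1))))
  }
})

test_that("near-miss negative controls never earn the targeted label", {
  for (v in c("V1", "V2", "V3")) {
    ncs <- negative_controls(v, TEST_CONFIG, seed = 77)
    expect_gte(length(ncs), 3)
    for (nc in ncs) {
      got <- label_of(nc$record, v)
      expect_equal(got, nc$expected, label = paste(v, nc$description))
      if (nc$targeted != nc$expected)
        expect_false(got == nc$targeted, label = paste(v, nc$description))
    }
  }
})

test_that("boundary values sit on the correct side of every threshold", {
  # troponin exactly 3 x ULN with a 410.7 code is not an nSTEMI (V2)
  expect_false(label_of(acute_record("410.7", trop_ratio = 3), "V2") == "NSTEMI")
  # EF 36% blocks systolic HF; EF exactly 35% qualifies
  expect_false(label_of(acute_record("428.0", bnp_ratio = 5, ef = 36), "V3") ==
                 "SYSTOLIC_HF")
  expect_equal(label_of(acute_record("428.0", bnp_ratio = 5, ef = 35), "V3"),
               "SYSTOLIC_HF")
  # BNP exactly at ULN does not qualify (strict >)
  expect_false(label_of(acute_record("428.0", bnp_ratio = 1, ef = 30), "V3") ==
                 "SYSTOLIC_HF")
})
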
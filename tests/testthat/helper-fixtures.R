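# Shared fixtures: the calendar-2010 surveillance period and a compact
# builder for single-admission records.

TEST_PERIOD <- period_of_interest("2010-01-01", "2010-12-31")
TEST_CONFIG <- algorithm_config(TEST_PERIOD)

dx_list <- function(codes, system = "ICD9CM") {
  if (is.list(codes)) return(codes)  # pre-built coded_diagnosis list
  lapply(codes, function(cd) coded_diagnosis(system, cd))
}

# One-hospitalization patient: discharge codes plus optional labs, echo,
# ECG and procedures linked to the stay.
acute_record <- function(codes, system = "ICD9CM", id = "P1",
                         enroll = "2007-01-01", admit = "2010-03-01",
                         stay = 3, elective = FALSE,
                         trop_ratio = NULL, trop_uln = 0.04,
                         bnp_ratio = NULL, bnp_uln = 100,
                         ef = NULL, acronyms = NULL, procedures = list()) {
  admit_dt <- as.POSIXct(paste(admit, "09:00:00"), tz = "UTC")
  disch_dt <- admit_dt + stay * 86400
  h <- hospitalization(admit_dt, disch_dt, elective = elective,
                       diagnoses = dx_list(codes, system),
                       procedures = procedures)
  labs <- list()
  if (!is.null(trop_ratio))
    labs[[length(labs) + 1L]] <- lab_result("TROPONIN", trop_ratio * trop_uln,
                                            trop_uln, admit_dt + 3600)
  if (!is.null(bnp_ratio))
    labs[[length(labs) + 1L]] <- lab_result("BNP", bnp_ratio * bnp_uln,
                                            bnp_uln, admit_dt + 7200)
  patient_record(id, enroll, hospitalizations = list(h), labs = labs,
                 ecgs = if (is.null(acronyms)) list()
                        else list(ecg_record(admit_dt + 1800, acronyms)),
                 echos = if (is.null(ef)) list()
                         else list(echo_record(admit_dt + 86400, ef)))
}

# label of a one-off classification
label_of <- function(record, version, config = TEST_CONFIG) {
  classify_patient(record, version, config)$label
}

# all category x version pairs (excluding the UNCLASSIFIED fall-through)
all_category_versions <- function() {
  do.call(rbind, lapply(c("V1", "V2", "V3"), function(v)
    data.frame(version = v, category = c(version_categories(v), "UNCLASSIFIED"),
               stringsAsFactors = FALSE)))
}
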
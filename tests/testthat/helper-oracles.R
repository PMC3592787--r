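# Independent oracles used by the code-matching and agreement tests.

# Every ICD-9-CM code string in the 410-429 / 786 rubric space at 3-, 4-
# and 5-digit granularity.
icd9_universe <- function() {
  rubrics <- c(410:429, 786)
  codes <- character()
  for (r in rubrics)
    codes <- c(codes, as.character(r), sprintf("%d.%d", r, 0:9),
               sprintf("%d.%02d", r, 0:99))
  codes
}

int_part <- function(code) as.integer(sub("\\..*$", "", code))
first_dec <- function(code) {
  if (!grepl(".", code, fixed = TRUE)) return(NA_integer_)
  as.integer(substr(sub("^[^.]*\\.", "", code), 1, 1))
}

# Set membership restated purely from rubric arithmetic (integer part and
# first decimal digit) — no reference to the implementation's rule kinds.
codeset_oracle <- list(
  HEART_DISEASE       = function(i, d) i %in% 410:414 || i %in% c(425L, 428L),
  STEMI_ICD9_DEFINITE = function(i, d) i == 410L && !is.na(d) && d %in% c(0:6, 8),
  MI_AMBIGUOUS        = function(i, d) i == 410L && !is.na(d) && d %in% c(7L, 9L),
  MI_ANY              = function(i, d) i == 410L,
  NSTEMI_410_7        = function(i, d) i == 410L && !is.na(d) && d == 7L,
  HF_CODES            = function(i, d) i %in% c(425L, 428L),
  OTHER_HEART_420_429 = function(i, d) i %in% 420:429,
  UA_CODES            = function(i, d) i == 411L || (i == 786L && !is.na(d) && d == 5L),
  CHEST_PAIN          = function(i, d) i == 786L && !is.na(d) && d == 5L,
  CHRONIC_V1          = function(i, d) i %in% c(412:414, 420:429),
  STEMI_IMO           = function(i, d) FALSE,  # ICD9CM never matches an IMO-only set
  NSTEMI_IMO          = function(i, d) FALSE,
  PACER_DEFIB         = function(i, d) FALSE   # procedure systems only
)

# kappa as a ratio of integers: with d the diagonal sum and
# S = sum_i (row_i x col_i), kappa = (n*d - S) / (n^2 - S) exactly.
kappa_int_oracle <- function(counts) {
  n <- sum(counts)
  d <- sum(diag(counts))
  S <- sum(rowSums(counts) * colSums(counts))
  if (n^2 == S) return(if (d == n) 1 else NA_real_)
  (n * d - S) / (n^2 - S)
}

rand_counts <- function(k, max_entry = 3) {
  matrix(sample(0:max_entry, k * k, replace = TRUE), k, k)
}
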
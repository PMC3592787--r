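---
title: "Methods: hierarchical EHR phenotyping of coronary and heart-failure events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical EHR phenotyping of coronary and heart-failure events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioevent)
```

## The classification model

`cardioevent` assigns each patient one event category per surveillance
period from structured EHR data alone: ordered discharge diagnosis codes
(ICD-9-CM or IMO interface terminology), troponin and BNP values relative
to their assay upper limit of normal (ULN), numeric ECG interpretation
codes, echocardiographic ejection fraction (EF), insurance claims with
place of service, and the enrollment start date.

The model is a **prioritized rule hierarchy**, not a probabilistic
classifier. Category criteria are evaluated independently
(`criteria_satisfied()`), and the final label is the highest-priority
satisfied category (`classify_patient()`). The clinical motivation is
that acuity dominates: an infarction complicated by acute heart failure
is recorded as the infarction, and acute categories always dominate the
ambulatory/chronic ones. `UNCLASSIFIED` is an explicit output, not an
error — screening rules select more charts than the categories absorb.

Three algorithm versions are provided because the available coding
systems changed across iterations:

* **V1** works from 4-digit ICD-9-CM plus troponin. At that granularity
  410.9 covers both STEMI and nSTEMI, and ECG statement codes were not
  searchable, so V1 reports a merged `MI_UNSPECIFIED` category.
* **V2** adds coded ECG interpretation statements (codes 964–968 denote
  ST elevation) to split STEMI from nSTEMI, an EF clause to the
  heart-failure criterion, chest-pain codes (786.5x) and a
  pacemaker/defibrillator-procedure exclusion to unstable angina, and
  claims-based ambulatory/chronic criteria.
* **V3** replaces the ECG route with IMO interface terminology — ICD-9
  -rooted codes refined by a fifth digit and letter suffixes, granular
  enough to be STEMI- or nSTEMI-specific (e.g. `410.90CP` vs `410.90BT`;
  `410.91` is nSTEMI except `410.91D`). V3 deletes unstable angina and
  merges ambulatory presentation with chronic disease.

### Episodes of care

Category criteria for acute events are evaluated per *episode of care*: a
hospitalization whose discharge date falls inside the period of interest,
together with the labs, ECGs and echos whose timestamps lie in
`[admit − 24 h, discharge + 24 h]`. The source data do not carry encounter
identifiers linking labs to stays, so linkage must be temporal; the
24-hour margin keeps pre-admission emergency-department troponins and
discharge-day echos with the stay they belong to clinically. This window
is a design choice of the package — no linkage rule is prescribed by the
criteria themselves — and one event may attach to several overlapping
episodes. Linkage is deterministic and idempotent.

## Parameters and their defaults

All thresholds live in `algorithm_config()`:

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `ef_threshold` | 35 | % LVEF | inclusive: EF = 35 qualifies, 36 does not |
| `troponin_multiplier_v1` | 1 | × assay ULN | strict: exactly 1×ULN does not qualify |
| `troponin_multiplier_v23` | 3 | × assay ULN | strict: exactly 3×ULN does not qualify |
| `min_observation_years` | 2 | 365.25-day years | inclusive (≥ 2) |
| `st_elevation_acronyms` | 964–968 | ECG statement codes | inclusive integer range |

Labs are compared against their own assay's ULN, never an absolute
concentration, so extracts from sites with different assays remain
comparable. Every inequality direction is taken literally and pinned by
boundary tests and by `negative_controls()`: records one unit on the
wrong side of each threshold must not earn the targeted label.

Interpretation choices that the criteria leave open, resolved here once:

* **Primary diagnosis** means position 1 of the discharge list; list
  order defines position.
* **"Heart disease"** for the ambulatory/chronic criteria means any
  diagnosis in rubrics 410–414 or codes 425/428, on a claim or a
  hospitalization, with the admission date standing as a
  hospitalization diagnosis date.
* **V1 ambulatory** ("no nonelective hospitalization at time of
  diagnosis") is operationalized as no nonelective admission within ±30
  days of the first heart-disease–coded event, with ≥ 2 years of prior
  observation; no window is prescribed by the criterion, and ±30 days is
  this package's reading.
* **V2 STEMI** attaches the troponin > 3×ULN condition only to the
  410.7/410.9 + ST-elevation-ECG branch; definite codes 410.0–410.6 and
  410.8 qualify on the code alone. The criterion text is ambiguous on
  this scope; the chosen parse mirrors the V3 cell, where definite codes
  also stand alone.
* **V2 ambulatory** is read literally as "first heart-disease claim is
  from an office, no earlier heart-disease claim, ≥ 2 years of
  observation before the period", without an extra requirement that the
  claim fall inside the period.
* **V3 ambulatory/chronic** does not exclude chest-pain (786.5)
  hospitalizations — only nonelective *heart-disease* admissions during
  the period disqualify; elective admissions never do.
* **Elective status is an input**, never inferred.
* Prefix code rules are registered in both the ICD-9-CM and IMO systems
  (IMO terms are ICD-9-rooted, so "any code starting with 410.7" is read
  across both vocabularies), but each individual rule still requires its
  own system: an IMO code never matches an ICD-9-CM rule. A bare
  `410.92` with no letter suffix belongs to neither IMO term list. Codes
  supplied without their decimal point (`"4109"`) are rejected as
  malformed rather than guessed. The IMO nSTEMI list is explicitly
  non-exhaustive in the source coding system; `read_codesets_yaml()`
  exists so sites can extend term lists without code changes.

## Agreement statistics

Validation against gold-standard (chart-review) labels uses the square
confusion matrix with algorithm labels on rows and gold labels on
columns. Observed agreement is the diagonal proportion; per-category
agreement defaults to algorithm-row denominators (agreement per
computer-identified case), with gold-column denominators as an option and
zero-denominator categories reported as undefined (`NA`), not 0.

Cohen's κ is `(p_o − p_e)/(1 − p_e)` with
`p_e = Σ_i row_i·col_i / n²`. The default confidence interval uses
Cohen's large-sample standard error

```
SE = sqrt( p_o (1 − p_o) / ( n (1 − p_e)² ) )
```

with normal quantiles and endpoints truncated to [−1, 1], reported at two
decimals. The Fleiss–Cohen–Everitt asymptotic variance is implemented as
`kappa_ci(..., method = "fleiss")` for users who prefer it; the simple
form is the default because it is the one whose two-decimal interval
matches the historical validation report this package reconstructs.
Degenerate cases are defined explicitly: κ = 1 when `p_e = 1` with
perfect agreement; an error when `p_e = 1` with imperfect agreement;
n < 2 is an error. Weighted κ is out of scope — the categories are
nominal.

The implementation is checked in the test suite against an independent
integer-arithmetic oracle, `κ = (n·d − S)/(n² − S)` with `d` the diagonal
sum and `S = Σ row_i·col_i`, exhaustively over all 2×2 tables with
entries 0–3 and over a large fixed-seed sample of 4×4 tables.

## What the synthetic generator emulates — and what it does not

`generate_patient()` builds, per category × version, a minimal record
satisfying exactly the targeted criterion, with jittered dates and
values. Jitter ranges are strictly interior to every threshold so a draw
can never flip a label: troponin ratios in (3.5, 20]×ULN under the 3×ULN
rule ((1.5, 20] under V1's 1×ULN rule), BNP in (1.5, 10]×ULN, EF uniform
in [15, 35]%. Admissions fall on uniform days inside the period with
2–6-day stays; enrollment starts 1000 days (≈ 2.74 years) before the
period so observation criteria are satisfiable with margin. One seed
drives the cohort, and each patient gets a derived substream keyed by
insertion index, so appending categories never changes earlier patients'
data.

Discordance injection reproduces algorithm-vs-reviewer disagreement
patterns: when the requested algorithm label outranks the gold category,
the gold scenario simply gains the algorithm category's trigger episode;
the one demotion pattern supported is the heart-failure admission coded
under an nSTEMI term in the primary position (the algorithm reads
nSTEMI; the clinical picture — elevated BNP, EF ≤ 35% — is heart
failure). Requested discordance pairs for which no perturbation exists
under the version's rules raise an explicit infeasibility error, and
every generated discordant record is verified by classification before it
is emitted, so requested and realized confusion matrices agree exactly.

The generator is **not** an EHR simulator. It has no age/sex structure,
no comorbidity correlation, no coding noise, no missingness, and its
records are minimal rather than realistic. Passing round-trip tests
therefore demonstrates that the classifier implements its stated criteria
exactly — not that it would achieve any particular agreement on real
extracts, where coding practice, assay reporting and chart ambiguity
dominate performance.

## Problem sizes and numerical notes

The test suite exercises: round-trip soundness over 100 seeds for every
category × version (with 25-seed versions in the module tests); hierarchy
precedence over every category pair per version, with the two source
scenarios placed in disjoint date windows so their episodes cannot share
events; code matching against a brute-force enumeration over the full
3/4/5-digit 410–429 and 786 rubric space (2331 codes); and the κ oracle
comparisons above. These sizes were chosen to make the properties
exhaustive where the space is finite and comfortably redundant where it
is not. All equality comparisons on statistics use a 1e-12 tolerance;
everything else is exact. Merging two category scenarios
(`merge_records()`) can legitimately void a record-level criterion — an
added admission may become the patient's first heart-disease diagnosis —
so the hierarchy property is asserted as "label = highest-priority
*satisfied* category", which is what the hierarchy states.

Dates are compared at day precision where the criteria speak in dates
(period membership, enrollment); timestamps are timezone-naive local
datetimes stored as UTC. Rubric-range comparison is numeric on the
decimal code string, so `410.10` sorts below `410.9`.

## Known limitations

* No ICD-10-era variant, no HL7/FHIR/OMOP ingestion, no free-text
  processing: the package consumes already-coded extracts in its
  JSON-lines schema.
* The IMO term lists ship as published; completeness depends on the site
  (use the YAML extension mechanism).
* Only the third iteration's validation table can be reconstructed
  exactly from published counts (its single disagreement is described);
  the first two iterations' off-diagonal structures are unknown, so
  their κ values are not reproduction targets — the acceptance script
  reports their overall and per-category agreement, which the printed
  counts do determine.
* The CI reproduces the historical report only under the default SE
  formula; the exact estimator used by the original statistics software
  is not documented there.
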
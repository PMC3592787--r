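# cardioevent

Rule-based classification of acute coronary and heart-failure events from
structured electronic-health-record (EHR) data — no chart review required.

## The problem

Public-health surveillance of heart disease traditionally depends on manual
record review: clinicians read charts and sort each event into categories
such as ST-elevation myocardial infarction (STEMI), non-ST-elevation MI
(nSTEMI), acute systolic heart failure, unstable angina, disease first
diagnosed in the ambulatory setting, or chronic prevalent disease. That is
slow and expensive. The data the reviewers use, however, are largely
structured: discharge diagnosis codes, troponin and BNP laboratory values,
coded ECG interpretation statements, and echocardiographic ejection
fraction (EF). `cardioevent` implements a computable phenotyping algorithm
over exactly those inputs, in three historical iterations, together with
the machinery to validate any of them against gold-standard labels and a
synthetic cohort generator so everything is testable without patient data.

The intended users are epidemiologists and clinical informaticists running
disease surveillance or decision-support pipelines over EHR extracts.

## The algorithm

Classification is hierarchical: each category's criteria are evaluated and
the highest-priority satisfied category wins, so a STEMI complicated by
acute heart failure is a STEMI. Inequalities are literal: troponin and BNP
thresholds are strict (`>`), the EF cutoff is inclusive (`≤ 35%`), and the
observation requirement is inclusive (`≥ 2` years, 365.25-day years).

| Priority | V1 (ICD-9 + troponin) | V2 (adds ECG codes, EF) | V3 (IMO terms) |
|---|---|---|---|
| 1 | unspecified MI: 410.x code + troponin > ULN | STEMI: 410.0–410.6/410.8, or 410.7/410.9 + ST-elevation ECG code (964–968) + troponin > 3×ULN | STEMI: code starting 410.0–410.6/410.8 or a STEMI-specific IMO term |
| 2 | systolic HF: primary 425/428 + BNP > ULN | systolic HF: + EF ≤ 35% | systolic HF: + EF ≤ 35% |
| 3 | unstable angina: 411.x, no troponin > ULN | nSTEMI: 410.7/410.9, no ST-elevation code, troponin > 3×ULN | nSTEMI: code starting 410.7 or an nSTEMI-specific IMO term |
| 4 | ambulatory presentation | unstable angina: 411.x/786.5x, no troponin > 3×ULN, no pacer/defibrillator procedure | ambulatory or chronic: heart-disease diagnosis, no nonelective heart-disease admission in the period |
| 5 | chronic prevalent disease | ambulatory presentation | — |
| 6 | — | chronic prevalent disease | — |

Anything not captured is `UNCLASSIFIED`. V1 merges STEMI and nSTEMI
because 4-digit ICD-9-CM cannot separate them (410.9 covers both) and ECG
codes were not searchable for that iteration; V3 resolves the ambiguity
with IMO interface terminology — ICD-9-rooted codes extended with a fifth
digit and letters (e.g. `410.90CP` is STEMI-specific, `410.91` except
`410.91D` is nSTEMI) — and drops unstable angina while merging ambulatory
and chronic disease into one category.

Validation uses the confusion matrix (algorithm rows × gold columns),
observed agreement `p_o = tr(M)/n`, per-category agreement, and Cohen's

```
κ = (p_o − p_e) / (1 − p_e),   p_e = Σ_i (row_i · col_i) / n²
```

with the large-sample 95% CI `κ ± z·SE`,
`SE = sqrt(p_o(1 − p_o) / (n(1 − p_e)²))` (the Fleiss–Cohen–Everitt
variance is available as an option).

## Worked example

Generate a synthetic cohort mirroring the third-iteration validation
design (50 STEMI, 50 nSTEMI, 34 systolic HF, 50 ambulatory/chronic, with a
single injected discordance: an acute-HF admission coded under an nSTEMI
IMO term), classify it, and validate against the generator's gold labels:

```r
library(cardioevent)

spec <- cohort_spec("V3",
  counts = c(STEMI = 50, NSTEMI = 49, SYSTOLIC_HF = 34, AMBULATORY_OR_CHRONIC = 50),
  discordance = data.frame(algorithm = "NSTEMI", gold = "SYSTOLIC_HF", count = 1),
  seed = 20100101)
cohort <- generate_cohort(spec)

cls <- classify_cohort(cohort$records, "V3", cohort$config)
summary(cls)
#> Cohort of 184 patient(s), algorithm V3
#>
#> AMBULATORY_OR_CHRONIC                NSTEMI                 STEMI
#>                    50                    50                    50
#>           SYSTOLIC_HF
#>                    34

validation_report(setNames(cls$label, cls$patient_id),
                  setNames(cohort$gold$label, cohort$gold$patient_id),
                  c("STEMI", "SYSTOLIC_HF", "NSTEMI", "AMBULATORY_OR_CHRONIC"))
#> Agreement report (n = 184)
#>   Observed agreement: 99.5% (183/184)
#>   Cohen's kappa: 0.99 (95% CI, 0.98-1.00)
#>   Per-category agreement (algorithm-row basis):
#>     STEMI                  100% (50/50)
#>     SYSTOLIC_HF            100% (34/34)
#>     NSTEMI                 98% (49/50)
#>     AMBULATORY_OR_CHRONIC  100% (50/50)
```

The one off-diagonal case is the injected discordant patient: the
algorithm reads the nSTEMI code in the primary position, while the gold
label reflects the heart-failure clinical picture (high BNP, EF ≤ 35%).

Cohorts are read and written as JSON-lines (`read_cohort()` /
`write_cohort()`), one patient object per line:

```json
{"patient_id":"P1","enrollment_start":"2007-01-01",
 "hospitalizations":[{"admit":"2010-03-01T09:30:00","discharge":"2010-03-04T15:00:00",
   "elective":false,"diagnoses":[{"system":"IMO","code":"410.90CP"}],"procedures":[]}],
 "labs":[{"analyte":"TROPONIN","value":0.61,"uln":0.04,"datetime":"2010-03-01T11:00:00"}],
 "ecgs":[],"echos":[],"claims":[]}
```

## Layout

- `R/` — domain model (`patient_record`, episodes of care), code-matching
  engine (`builtin_codesets`), the three classifiers (`classify_patient`),
  agreement statistics (`validation_report`), synthetic generator
  (`generate_cohort`, `negative_controls`), file I/O.
- `vignettes/phenotyping-methods.Rmd` — the methods notes: model
  assumptions, thresholds, design choices, limitations.
- `tests/testthat/` — unit, property and acceptance tests (enumeration
  and integer-arithmetic oracles live in `helper-oracles.R`).
- `inst/cli/cardioevent.R` — command-line wrapper.
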
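---
title: "Predicting 30-day unplanned readmission with weather exposure scores: methods"
author: "readmitw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 30-day unplanned readmission with weather exposure scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Unplanned readmission within 30 days of discharge is a standard indicator of
care quality, and ambient conditions — heat and cold waves, heavy rain,
dryness, and particulate air pollution — plausibly modify the risk for
elderly patients with weather-sensitive disease (mental/behavioural,
circulatory, respiratory, musculoskeletal). `readmitw` implements a complete,
testable pipeline for this prediction problem over a CDM-lite extract of an
electronic health record: five flat tables (persons, visits, conditions,
drugs, locations) modelled on the OMOP common data model, joined to daily
station weather and air-quality records through the patient's residence
postal region.

Because hospital EHR extracts are private, the package carries a first-class
synthetic generator (`generate_study()`) that produces two hospital sites —
a training site and a shifted external-validation site — with a *known*
logistic readmission mechanism, so every claim the pipeline makes can be
checked against planted ground truth.

## Cohort definition

An **index admission** is any hospitalization (inpatient or emergency) of a
patient aged at least 65 at admission, discharged alive, with the discharge
date inside the analysis window and a residence resolvable to a region with
weather coverage. The **outcome** is an emergency-route admission of the
same person at the same site with admit date in `(discharge, discharge+30]`
days that is not matched by the planned-care code lists (chemotherapy,
organ transplant, rehabilitation, following the CMS hospital-wide
readmission measure's planned/unplanned split). Conventions that the
problem leaves genuinely open were pinned as follows and are enforced by
tests:

* a visit beginning on the discharge day itself is a transfer, not a
  readmission; day +30 counts, day +31 does not (half-open `(0, 30]`);
* each qualifying discharge is its own index event, even when it falls
  inside an earlier event's open outcome window;
* the principal diagnosis is the earliest-dated condition of the stay (the
  admission diagnosis); its ICD-10 chapter (F/I/J/M, else "other") is the
  disease group, and `subgroup_cohorts()` allows multi-chapter membership;
* seasons are meteorological (Mar–May spring, and so on);
* the "60s" age band is 65–69, because inclusion starts at 65.

**Covariates** are age (continuous and banded), gender, season, length of
stay, the Charlson comorbidity index, and binary indicators for condition
and drug *eras*. Eras collapse repeated occurrences of one concept into
continuous periods under an inclusive 30-day persistence gap (the OHDSI
convention; the gap is an argument). Condition concepts are grouped at the
3-character ICD-10 level and drugs at the ingredient code — a vocabulary-
level rollup would need concept tables the package deliberately does not
depend on. The covariate lookback ends at the index discharge date. The
alternative literal reading — conditions up to the end of the readmission
interval — would leak outcome-window information into a covariate, so it is
available only behind an explicit switch (`include_outcome_window`).

The Charlson score uses a Romano-style ICD-10 prefix mapping shipped as an
editable CSV (17 categories, weights 1/2/3/6), with severity hierarchies:
complicated diabetes supersedes uncomplicated, severe liver disease mild,
metastatic tumor non-metastatic malignancy. Ambiguous prefixes resolve by
longest match. The mapping file is data, not code, so other adaptations
(Deyo, Quan) can be dropped in.

## The W-score

For each index event the W-score summarises forecastable weather stress
over the 7 days starting at the discharge date (day 0 included — the score
is designed so a 7-day forecast available at discharge could be substituted
for the observed series). Station records are first harmonized to
per-region daily series (cross-station median per region/day/element), and
remaining missing region-days are filled with the average of that element's
regional daily values over the window, flagged as imputed.

Each of five elements — PM10, rainfall, relative humidity (dryness),
minimum temperature (cold wave), maximum temperature (heat wave) — is
scored daily against advisory/warning criteria in the style of special
weather reports: `warning_points` (default 2) when the warning criterion is
met, else `advisory_points` (default 1) when the advisory criterion is met,
else 0. Multi-day persistence requirements (heat, cold, dryness default to
2 days) are evaluated retrospectively: a tier fires only on a day ending a
qualifying run at that tier's threshold. The element's W-score is the sum
of its daily points over the 7-day window. The shipped thresholds (heat
33/35 °C, cold −12/−15 °C, dryness 35/25 %RH, heavy rain 80/150 mm, PM10
150/300 µg/m³) live in `warning_criteria()`/`criteria.yaml`-style config:
the engine is threshold-agnostic, and a reading of the score as summed raw
meteorological values rather than graded points is a config change, not a
code change. PM2.5, SO2, NO2 and O3 are ingested and exported but never
scored: PM2.5 is collinear with PM10 and patchier in source data.

## Models and validation

Feature matrices come in two configurations — `clinical` and `clinical_w`
(clinical plus the five W elements, a purely additive block) — with a
deterministic column order and a persisted manifest. External-site matrices
are conformed to the training manifest: unseen concepts dropped, missing
concepts zero-filled. Era columns with fewer than 10 positive training
cells are pruned (configurable).

Four tree-based families are trained: decision tree (`rpart`), random
forest (`ranger`), AdaBoost, and gradient boosting (`xgboost`). The
AdaBoost family is a SAMME boosting loop written in the package over rpart
depth-1 stumps, since no boosting wrapper package is available; the base
learner is still a standard implementation. Default hyper-parameter grids
are config:
DT explores class weighting (balance/none) at depth 10; RF crosses depth
{4, 10, 17} with per-split features {√p, 5, 20} at 500 trees; ADA uses
learning rate 1 with 4 estimators; GBM crosses learning rate
{0.005, 0.01, 0.1}, depth {4, 6, 17} and trees {100, 1000} with 25
early-stopping rounds (on a seeded internal 10% partition) and minimum node
size 2.

Model selection is grid search by stratified 10-fold cross-validated AUROC
on a stratified 75/25 train/test split (the split fraction is this
package's choice). Ties keep the first
grid row in declared order. The selected configuration is refit on the full
training part; the held-out internal AUROC and the frozen-model external
AUROC (no refitting, conformed matrix) are reported, along with ROC point
files, a model-by-mode AUROC table with best-per-column flags, and a
per-covariate summary (overall/with-outcome/without-outcome means sorted by
absolute separation). AUROC is computed by the rank (Mann–Whitney)
formulation, ties counting one half, and errors rather than defaulting when
a class is absent.

## The synthetic generator

`sim_config()` defaults define the study conditions: two sites of elderly
inpatients (ages uniform 60–99 at window start, so the ≥65 filter makes
genuine exclusions) over the two calendar years 2017–2018, five postal
regions with small climate offsets, a disease-group mix (F 9%, I 26%,
J 28%, M 37%) plausible for an elderly inpatient case mix across the four
weather-sensitive chapters, geometric lengths of stay (mean 2 days, cap
14), and a seasonal sinusoid-plus-noise climate with a late-July
temperature peak, summer-peaking humidity and rainfall, and log-normal
PM10 with winter elevation producing episodic advisory-level exceedances —
a temperate monsoon-influenced metropolitan climate. Weather is generated
per station; multi-station regions exercise the cross-station median.

Outcomes are planted by a logistic model on the TRUE covariates, including
the true W-score recomputed from the generated series by the exposure
module itself: `logit p = intercept + β_age(age−80) + β_los(los−2) +
β_cci(cci−1) + β_group + β_w·W`. Defaults were calibrated once to
statistics typical of elderly tertiary-care readmission cohorts
(readmission incidence ~10–16%, mean Charlson ~0.5–1.1, mean stays of a
few days) and then frozen: intercept `qlogis(0.09)`, β_age 0.025, β_los
0.07, β_cci 0.25, group effects 0–0.3, and a default weather effect
concentrated on PM10, rainfall and maximum temperature — the elements most
consistently implicated in weather-sensitive readmission.

Two generator properties matter for testing. First, every artefact has its
own seeded stream (per site and per table), so adding persons never
perturbs the weather. Second, a person's spontaneous admissions are spaced
at least 80 days apart with stays capped at 14 days; combined with the
30-day outcome window and ≤3-day readmission stays, the only visit that can
fall inside an index event's outcome window is that event's own planted
readmission. Label recovery against the truth record is therefore *exact*,
which the tests assert.

What the generator does **not** emulate: realistic ICD-10 co-occurrence
structure, pharmacology, spatial correlation of weather between regions,
cross-site patient overlap, or seasonal admission rates. Passing tests
therefore demonstrate the pipeline's correctness and its ability to recover
planted signal — not clinical performance on real data, which can only be
established against private hospital EHR databases.

## Scenario definitions used by the acceptance checks

* **Null calibration**: all outcome coefficients zero, intercept
  `qlogis(0.1)`, 5,000 persons per site — internal test AUROC must sit in
  0.5 ± 0.05 (no signal, no skill).
* **Strong weather signal**: under the shipped criteria the PM10 element is
  a rare-event count (window mean ~0.2 points, sd ~0.55), so a "strong" W
  effect is defined as a contribution comparable to a major clinical
  covariate: β_w = (PM10 0.8, rainfall 0.4, tmax 0.4) per point — an odds
  ratio of ~2.2 per PM10 advisory day — with moderate clinical effects
  (β_age 0.05, β_los 0.12, β_cci 0.45, group effects 0.2–0.5). The
  true-model AUROC under this scenario is ~0.72, leaving headroom for a
  learned model to clear 0.65 and for the W-augmented model to beat the
  clinical-only model consistently across seeds.
* **Problem sizes**: oracle-equivalence checks run 1,000 random instances
  per operation; pipeline checks use 5,000 persons per site with a compact
  GBM grid (learning rate {0.1, 0.01} × depth {4, 6}, 300 trees, early
  stopping 25) — grids are config, and the Table-style default grid remains
  the package default. The byte-determinism check runs the full
  simulate→cohort→W-score→featurize→train→report chain twice at 300
  persons and compares every emitted file.

## Numerical and degenerate-input choices

* Dates are calendar days throughout; no times, no time zones.
* The era gap comparison is inclusive (`distance ≤ gap` merges); boundary
  behaviour is pinned by tests at gap−1/gap/gap+1.
* Imputation can in principle leave an imputed minimum temperature above
  the same day's observed maximum; imputed tmin is capped at tmax so the
  per-day ordering survives.
* An element never observed in a region is a fatal imputation error; an
  element absent from the ingested data entirely simply scores zero.
* Persistence runs reset across calendar gaps in a series (relevant only
  for hand-built partial series; harmonized series are gap-free).
* AUROC with a single class present, empty hyper-parameter grids,
  unconformed external matrices, and unresolvable foreign keys are all
  errors, not defaults.
* `with_seed()` sandboxes every internal use of randomness and restores
  the caller's RNG state.

## Known limitations

* The planned-readmission lists are prefix lists (chemotherapy, transplant,
  rehabilitation), not the full CMS procedure-category algorithm.
* Readmissions are detected within one site's bundle only; cross-site
  readmission is out of scope by design.
* The W-score uses the observed post-discharge series; the deployment
  reading (feeding a 7-day forecast at discharge) is supported by the same
  scoring functions but no forecast ingestion is provided.
* The Romano-style ICD-10 map is an adaptation shipped for auditability; it
  is not a transcription of any single published table.
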
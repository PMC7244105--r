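---
title: "Reconstructing treatment lines from pharmacy claims: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing treatment lines from pharmacy claims: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppplines)
```

## The problem

Palmoplantar pustulosis (PPP, ICD-10 L40.3) is a chronic relapsing
inflammatory skin disease treated with topical agents, phototherapy,
non-biologic systemic drugs and — for patients with coexisting immune
disease — biologics. Administrative claims databases record dispensings,
procedures and costs but not treatment intent, so describing treatment
patterns requires *reconstructing* lines of therapy from dated claims:
deciding when an exposure started and ended, when a gap means
discontinuation rather than a late refill, when overlapping drugs are a
combination regimen rather than a switch in progress, and how each line
ended. `ppplines` implements this reconstruction as a configurable,
testable pipeline and ships a synthetic claims generator with planted
ground truth so every rule can be validated end to end.

## Cohort selection

The index date is a patient's first PPP diagnosis claim inside the study
window (default 2011-01-01 to 2017-03-30). Patients are eligible when they
have a confirmed diagnosis (at least two PPP claims; by default two
same-day claim records count, `require_distinct_dates` demands distinct
days), are at least 18 at index, and have continuous enrollment covering
183 days (6 months) before and after index. Follow-up runs from index to
the earlier of disenrollment and the study end. Patients failing several
criteria are counted once, under the fixed precedence *no confirmed
diagnosis → under 18 → insufficient pre-index enrollment → insufficient
post-index enrollment → special-management condition*; the last is a
configurable ICD-10 prefix list that is empty by default, since no
concrete code set defines "conditions requiring intensive or special
clinical management".

Treatment experience is classified from the 6-month wash-out window:
*naive* patients have no treatment claim (disease-directed prescription or
phototherapy) before index, *experienced* patients have at least one, and
patients with no treatment claim at any time are *not applicable*.
Severity has no accepted clinical scale in claims, so treatment is used as
a proxy, assessed over the **entire** follow-up: patients whose observed
line-level classes are a subset of `{topical}` (including none) are
*mild*; anything else (phototherapy, systemic or biologic exposure) is
*moderate to severe*.

Baseline description includes the Charlson comorbidity index, computed
from a Quan-style ICD-10 prefix table shipped as editable data
(`default_cci_map()`). Prefix groups are matched independently and each
matched group contributes its weight once; the classical hierarchy rules
(e.g. metastatic disease superseding localized malignancy) are *not*
applied — a deliberate simplification of a configurable map, not a claim
of fidelity to any single published algorithm. Polypharmacy counts
distinct ATC prefixes in the wash-out window at hierarchy level 1
(1 character) and level 3 (4 characters, e.g. `A01A` vs `A01B`).

## Exposure model

Every claim becomes a half-open exposure interval `[start, end)` in whole
days; printed durations are `end − start`, which removes the ±1-day
ambiguity of inclusive conventions.

* one **topical** fill covers 14 days (`topical_duration_days`);
* one **phototherapy** session covers 28 days
  (`phototherapy_duration_days`), reflecting its scheduled delivery;
* **systemic and biologic** fills cover the dispensed days supplied
  (`ddd_days`, derived from WHO defined daily doses), falling back to
  `systemic_default_days = 30` when absent;
* a missing dispense date is imputed as the claim-record date — the
  simplest defensible reading of "estimated prescription date", and
  configurable by editing the table before the pipeline runs;
* same-day duplicates of one drug are counted once and logged.

Prescription categories reduce onto four line-level classes: topical;
phototherapy; non-biologic systemic (which absorbs retinoids, systemic
corticosteroids and qualifying antibiotics); and biologic. Category
`other` — all background medication — never takes part in line
construction. **Antibiotics** (macrolides, tetracyclines) are
disease-directed only as long courses: their exposures are grace-merged
among themselves and count as systemic therapy only when the merged spans
total at least `antibiotic_min_days = 31` days ("more than one month");
shorter courses are excluded entirely. Days bridged by the grace period
count toward that total, since the merged span is the unit the rest of
the algorithm reasons about.

## Grace period, overlaps, segmentation

Within each class, consecutive exposures merge when the refill gap is at
most the **grace period** (maximum allowed gap duration,
`grace_period_days = 61`); the merged span covers the gap. Overlap between
two topical products is never concomitant therapy — they already share
one class.

Two arbitration rules then adjust the merged per-class exposures:

1. **First-line topical truncation.** When topical therapy strictly
   precedes every other class, the initial topical exposure is cut at the
   start of the first phototherapy or oral-systemic exposure: the patient
   is assumed to have stopped the topical when escalating. Biologic
   (injection) starts do not trigger the cut. Corticosteroid-flagged
   topical exposures are exempt, because stopping corticosteroids may
   require progressive dose tapering; the flag propagates through merges
   if any merged fill carried it. Topical therapy that starts *with or
   after* another class is left alone — later-line topical accompaniment
   is a real regimen feature, reported as the "with topical therapy"
   breakdown.
2. **Phototherapy/systemic overlap.** An overlap longer than
   `combination_overlap_days = 14` keeps both exposures and marks the
   resulting line as combination therapy. A shorter, nonzero overlap is
   read as a switch in progress: the earlier-starting exposure is
   truncated at the later one's start. Exposures starting the same day are
   kept (ties open one line with the union regimen).

Treatment lines are the maximal intervals over which the set of
concurrently active classes is constant and nonempty; a new line begins at
every change-point that survives these rules. Under half-open day
arithmetic a regimen change shorter than one day cannot occur.

Each line's terminating event is labelled from its successor: no activity
within the grace period after the line ends — while follow-up continues
past `end + grace` — is a **discontinuation**; a successor within grace is
an **add-on** if its regimen strictly grows, a **reduction** if it
strictly shrinks (the narrow reading of an otherwise undefined term — an
interpretation, flagged as such), and otherwise a **switch** (replacement
dominates mixed changes, consistent with switching being the dominant
observed event). A line still active at the end of follow-up, or whose
grace window is cut off by censoring, is **no change**. The grace period
is thus used *within* classes for merging and *across* classes only for
event labelling — the reading we adopted where the source rules are
ambiguous. Tonsillectomy and granulocyte/monocyte apheresis are recorded
as medical interventions alongside lines but never define one.

## Resource use, costs, time to event

Utilization is summarized per resource kind (outpatient visits,
admissions, X-ray, MRI, CT, bone scintigraphy) as the share of patients
with at least one occurrence and as per-patient monthly rates — count
divided by follow-up months, with `month_length_days = 365.25/12` since
"per month" is otherwise undefined. Rate summaries follow the
users-only convention (among patients with at least one occurrence), with
the all-patient and pooled (total events over total patient-months)
variants emitted alongside, clearly labelled. Costs in yen are summed per
patient by category — inpatient, outpatient (visits, imaging,
phototherapy), pharmacy — and divided by follow-up months; the total is
the per-patient sum of the three categories before averaging.

Time-to-event outcomes (first occurrence per resource kind, first
discontinuation) use the package's own Kaplan–Meier product-limit
estimator; patients reaching the end of follow-up without the event are
censored there, and at tied times events precede censorings. A numerical
detail: the running product is kept as a reduced integer fraction (flushed
to a floating prefix before its terms could lose integer precision), so
that with no censoring the telescoped curve equals the empirical survivor
fraction `(n−k)/n` bit for bit. The `survival` package serves as an
independent cross-check in the test suite, never as the implementation.

## The synthetic generator

`synth_claims()` emulates the structure of an employer-based claims
extract: per-patient enrollment spans with demographics, diagnosis claims
(two confirm the disease; background comorbidity codes planted at
realistic frequencies), category-labelled prescriptions with refill
schedules, phototherapy sessions, Poisson-process utilization events with
lognormal costs, and a truth table holding every planted line, event,
severity class and experience flag. Ten archetypes cover every first-line
class, every terminating event, a within-line refill gap, a
combination-therapy line, the first-line topical truncation and a
never-treated patient. Planted trajectories are deliberately
unambiguous — transition gaps of 0–20 days versus discontinuation gaps of
100 days around the 61-day grace, overlaps of zero or a full line around
the 14-day combination threshold — so that recovery can be demanded
exactly, for 100% of patients. Monthly event rates (3.0 outpatient
visits, 0.05 admissions, 0.10 X-ray, 0.06 MRI, 0.16 CT, 0.05
scintigraphy) sit at the scale reported for this population.

What the generator does **not** emulate: seasonal or duration-dependent
refill behaviour, dose titration, claim-coding noise, correlated
comorbidity structure, or marginal demographics matched to any real
cohort. Passing recovery tests therefore demonstrates that the
reconstruction rules are implemented exactly as specified — not that the
rules themselves identify clinical intent in noisy real-world data, where
ambiguous gaps and overlaps are common and the grace-period convention
materially shapes the results.

## Validation strategy and problem sizes

Three independent routes check the core algorithm: (1) recovery of
planted ground truth on 2,000 synthetic patients (boundaries, regimens,
events, severity, experience — all exact); (2) equivalence with a literal
day-by-day simulation of the same rules on 1,000+ random small patients
(≤ 8 claims, ≤ 400-day horizons), which exercises arbitrary overlap and
gap configurations the archetypes avoid; (3) hand-computed fixtures for
the estimators (product-limit curves, per-month rates and costs to 1e-9)
plus agreement with `survival::survfit` to 1e-12 on 200 random censored
samples. Attrition counts are checked exactly against planted exclusion
fractions, and the assembled report is checked structurally: every cell
category present, partition percentages summing to 100 ± 0.1. These sizes
keep the whole suite at a few minutes on one CPU while leaving each check
statistically meaningful; they are the package's chosen validation
conditions, stated here so they can be scaled up.

## Known limitations

* Severity is a treatment proxy; it cannot distinguish undertreated
  severe disease from mild disease.
* The grace period, exposure windows and combination threshold are
  conventions; results are sensitive to them and the config makes them
  explicit rather than hiding them.
* "Reduction" has no operational definition in the source literature;
  strict regimen-subset within grace is our reading.
* No adherence metrics (MPR/PDC), no dose-tapering model beyond the
  corticosteroid exemption, no indirect costs.
* The drug-to-category map ships as a small generic-name table; real
  national drug dictionaries must be supplied by the user.
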
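---
title: "Comparing size, marker and perfusion response criteria in ovarian cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing size, marker and perfusion response criteria in ovarian cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dectresponse)
```

## The problem

High grade serous ovarian cancer (HGSOC) spreads diffusely over peritoneal
surfaces, so the standard size-based response assessment (RECIST 1.1, built
on the sum of longest diameters of a few target lesions) often reads
"stable disease" in patients who are clearly improving or deteriorating.
Two complementary signals exist: the serum marker CA125, formalized in the
GCIG response/progression rules, and — on dual-energy CT (DECT) — the
iodine concentration inside a lesion, a surrogate for vascularity that can
fall sharply under effective therapy while the lesion's water-logged bulk
stays the same size or even grows.

`dectresponse` implements all three criteria as formal, auditable engines
over a common longitudinal data model, derives per-criterion
progression-free survival (PFS), and compares responder vs non-responder
survival with Kaplan–Meier curves, log-rank tests and hazard ratios. A
synthetic-cohort generator supplies patient-level data with the statistical
structure the analysis assumes, since the motivating study's raw data are
not public.

## The three engines

### Size (RECIST 1.1 as commonly simplified)

At each imaging timepoint the sum of longest diameters (SLD) of the target
lesions, in mm, is compared with the baseline scan (the latest scan on or
before treatment start). With
$\Delta = 100\,(\mathrm{SLD}_t - \mathrm{SLD}_0)/\mathrm{SLD}_0$:

* new lesions force PD;
* SLD $= 0$ is CR;
* $\Delta \le -30$ is PR;
* $\Delta \ge +20$ is PD;
* otherwise SD.

Both thresholds are inclusive. Progression is referenced to **baseline**,
which is how the source analysis states its rule; full RECIST 1.1
references the nadir SLD and additionally requires a 5 mm absolute
increase. We implement the baseline simplification as the default (to
reproduce the analysis we model) and the strict nadir rule behind
`pd_reference = "nadir"`. A lesion diameter of 0 means "disappeared"; a
lesion that is simply unmeasured at a follow-up makes the timepoint NE
unless `carry_forward = TRUE`, because silent imputation hides data errors.

### CA125 (GCIG rules)

A patient is evaluable only if the pre-treatment sample (latest sample at
most 14 days before treatment start; the window is configurable, the source
says only "a pre-treatment sample") is at least $2\times$ the assay upper
limit of normal (ULN). Response requires a post-treatment sample at or
below half the pre-treatment value, confirmed $\ge 28$ days later with no
intervening breach. Progression requires a rise to at least $2\times$ the
ULN for patients whose marker normalized (nadir $\le$ ULN), or $2\times$
the nadir otherwise, on two occasions at least 7 days apart. "Twice the
nadir value or ULN" is ambiguous as printed; we adopt the standard
Rustin/GCIG disambiguation just stated. The threshold is frozen at the
first qualifying sample; the progression date is that sample's date. CR and
PR are not distinguished (the engine emits PR and flags normalization in
the audit detail), matching how the results we model were reported.

The laboratory ULN of the motivating study is not stated anywhere; the
package defaults to 35 U/mL, a common assay value, and every function
accepts an override.

### Iodine concentration (DECT)

Lesion iodine concentration (mg/mL) is normalized by dividing by the aortic
iodine concentration on the same scan ("normalizing to the aorta" could
also be read as a subtraction; the ratio is scale-free under contrast-dose
variation, which is the point of the correction, so the ratio was chosen).
Per-lesion normalized values are aggregated by summation across target
lesions, mirroring the SLD convention, with a mean mode behind a flag — the
source never states its multi-lesion aggregation. With threshold $\theta$
(default 15%):

* $\Delta \ge +\theta$: PD (non-responder);
* $\Delta \le -\theta$: PR;
* otherwise SD.

Responder status is simply "not PD", so an increase of 0–15% still counts
as responder — implied by SD being grouped with responders in the survival
analysis we model, adopted but not asserted. The observation that *any*
decrease tracked clinical improvement is surfaced as an `any_decrease`
flag, not as a category. `threshold_sweep()` re-classifies a training
cohort at candidate thresholds (default 10/15/20%) against a reference
non-responder label and selects the threshold with maximal balanced
accuracy, ties broken toward the larger (more conservative) threshold.

### Clinical override

Whatever the imaging category, a patient who changes therapy or dies
within 6 months of the follow-up examination did not benefit:
`reclassify_nonresponders()` forces the responder flag to `FALSE` (the
category itself is kept, and the override is recorded in the audit trail).
"Six months" is fixed at 182 days so tests are bit-exact.

## Survival comparison

PFS runs from treatment-line start to the criterion's first progression
date, in months computed as days$/30.4375$ (mean Gregorian month — again
for determinism). Without progression, the patient is censored at the
earliest of last follow-up, death and the next line's start; death before
that bound is an event by default (the PFS convention), and can be censored
instead, since the source does not state its handling. Mid-treatment scans
are classified against the line's baseline and may carry the progression
date; the per-line category comes from the last scan.

The Kaplan–Meier median is the smallest time with $S(t) \le 0.5$. The
log-rank test uses the conditional hypergeometric variance for ties, plus a
permutation mode (exhaustive up to 20 000 label assignments, Monte Carlo
beyond) for small samples where the $\chi^2_1$ approximation is rough. The
hazard ratio defaults to the Mantel–Haenszel $(O_1/E_1)/(O_2/E_2)$ from the
log-rank table with a log-normal CI using $\mathrm{Var}(\log HR) \approx
1/E_1 + 1/E_2$ — the estimator printed by the software used in the
analysis we model — with Cox partial likelihood behind `method = "cox"`.
P-values are reported to 4 decimals and no multiple-testing correction is
applied across the three per-criterion tests.

The survival comparison defaults to the relapse subset, the population on
which the iodine criterion was developed; `subset = "all"` includes
first-line patients.

## The synthetic cohort

`simulate_cohort()` draws, per patient, a latent responder status
(default probability 0.69, echoing the fraction with an iodine decrease in
the motivating cohort), a treatment setting (80% relapse), 1–5 target
lesions with log-normal baseline diameters (median 30 mm) and normalized
iodine ratios, and an exponential progression time with scale 10 months
for responders and 5 for non-responders (medians ≈ 7 and 3.5 months,
echoing — not matching — the printed medians). Treatment shifts each
quantity by a per-line step: −30% SLD / −30% normalized iodine for
responders, +25% / +30% for non-responders, with CA125 drifting
log-linearly at −0.55 or +0.35 per month from a log-normal pre-treatment
value (median 300 U/mL). Imaging happens at baseline and ~3 and ~6 months
(±10 days), CA125 monthly, everything truncated at death or a 12-month
administrative horizon. Measurement noise is multiplicative log-normal
(mean 1, CV 0.10 by default) — the natural noise model for strictly
positive quantities. Aortic iodine is drawn per scan, so normalization
genuinely matters in tests. All defaults live in `simulation_config()` and
were fixed once, from the printed cohort structure or from what a typical
relapsed-HGSOC cohort looks like, not tuned to any test.

What the generator does **not** emulate — and hence what a green test does
not establish:

* treatment effects are a step from baseline, not a trajectory: a
  responder's iodine never rises again at their eventual progression, so
  classification-derived progression dates for simulated responders arise
  only from death or censoring and simulated responder KM medians are
  often "not reached". Parameter-recovery checks for the hazard ratio
  therefore use the latent progression times
  (`truth_survival_records()`), not the classified ones;
* lesion count is fixed within a patient (no new lesions), so the RECIST
  new-lesion branch is exercised by hand-built fixtures only;
* biomarker trajectories are conditionally independent given the latent
  status; real size/iodine/CA125 correlations are richer;
* no inter-reader variability, no missing-at-random scan gaps, no
  mucinous/borderline marker behaviour.

`simulate_sweep_data()` is a separate, deliberately minimal fixture for
the threshold sweep: responder percent changes centred at 0%,
non-responders at +30%, equal SDs, so the generative decision boundary
sits exactly at +15% and the sweep should select 15.

## Numerical conventions

* Percent changes keep full precision internally; reporting rounds half
  away from zero (`round_half_up()`), so 62.5% prints as 63% — matching
  the printed tables we reproduce.
* All classification boundaries are inclusive.
* Dates are ISO-8601 calendar dates; durations are exact day counts.
* Degenerate log-rank instances (no informative event time) return
  $\chi^2 = 0$, $p = 1$ with a warning; a zero-event group makes the HR CI
  unbounded and flagged rather than silently dropped.

## Known limitations

The engines reproduce the *stated* rules of the analysis they model,
including its RECIST simplification (baseline-referenced PD); strict
RECIST 1.1 differs and is available but not the default. The printed
headline survival numbers (median PFS 7 vs 4 months under the iodine
criterion, HR 0.1) cannot be reproduced because the underlying 40-patient
dataset is unpublished; the package's acceptance surface is therefore the
exactly recomputable count-derived fractions plus property-based checks
(oracle equivalence, parameter recovery, threshold-sweep sanity) on the
synthetic world.
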
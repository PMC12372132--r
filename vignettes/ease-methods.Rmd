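---
title: "Methods: composite atrial risk scoring, simulated cohorts, and recurrence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite atrial risk scoring, simulated cohorts, and recurrence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easescore)
```

## The score and its assumptions

The package computes a six-parameter echocardiographic composite for
recurrence risk after pulmonary vein isolation in paroxysmal atrial
fibrillation. Each parameter measures one axis of left atrial remodeling:
reservoir strain (LASr, %) for compliance and fibrosis, the
electromechanical conduction time (PA-TDI, ms) for electrical remodeling,
the volume index (LAVI, mL/m²) for structural dilation, the E/e′ ratio
for filling pressure, the derived stiffness index E/e′/LASr for the
interaction of load and compliance, and contractile strain (LASct, %) for
booster-pump function. Inputs are already-measured numbers; the package
deliberately does no image processing.

Each parameter maps through ordered threshold bands to points, and the
total (0–12) maps to a risk category. The scheme assumes the published
clinical cutpoints (LASr 15/23, PA-TDI 120/150, LAVI 34/48, stiffness
0.5, E/e′ 14, LASct 6) and equal weighting of parameters. The literature
this score descends from states the band cutpoints and the 0–12 range but
not the per-parameter point values; we reconstruct the unique equal-weight
assignment consistent with both — 0/1/2 for the three parameters with
stated normal/borderline/severe bands, 0/2 for the three with a single
cutpoint. This reconstruction is a design choice, exposed entirely through
`ease_config()` so any other weighting can be configured and validated
with `validate_config()`.

Two category-boundary conventions circulate for the same score: 0–3 /
4–8 / 9–12 and 0–3 / 4–7 / 8–12. The interpretation table and the prose
agree on the first, which is therefore the default; the second is
preserved as a named alternate (`ease_config_fig6()`,
`inst/extdata/ease_fig6.yaml`) rather than declared wrong.

### Numerical conventions

* **Band edges.** Thresholds stated as strict comparatives are honoured
  literally: "greater than 23" makes (23, ∞) the normal band, so exactly
  23 is borderline; "below or equal to 0.5" keeps exactly 0.5 normal
  stiffness. Every edge is exactly representable in binary or resolved on
  one deterministic side — no tolerance fuzzing, so scoring a patient
  twice is bit-identical.
* **Missing LASct.** Contractile strain cannot be measured in AF at exam
  time. The default policy refuses to score (`refuse`) rather than invent
  data; `worst_case` (2 points, flagged) and `omit_rescale` (five-parameter
  total rescaled to 0–12, half-up rounding, flagged) are available when a
  score must be produced.
* **Degenerate inputs.** Non-positive measurements are rejected at the
  domain boundary (stiffness needs LASr > 0); malformed CSV rows are
  collected into a per-row error report instead of aborting the file.

## The synthetic-cohort generator

No cohort data are deposited for this class of score, so the generator is
the package's test bed: it emulates a single-centre cohort of 128
first-time ablation patients, and every downstream stage is exercised
against it.

Per patient, a latent remodeling severity (mild / moderate / severe) is
drawn with weights (0.30, 0.47, 0.23), chosen to reproduce the reported
category mix of roughly 30/48/23 %. Conditional on severity, the five
primitive parameters are normal draws shifted by a single shared
standard-normal latent factor whose loadings are signed toward
abnormality (negative for the two strains), then clamped at physiologic
floors (LASr ≥ 2 %, PA-TDI ≥ 60 ms, LAVI ≥ 10 mL/m², E/e′ ≥ 2,
LASct ≥ 0.5 %). The shared factor is the simplest structure that produces
both the marginal band occupancies and the observed cross-parameter
correlation pattern, in particular the strong negative reservoir-strain ↔
stiffness relationship (target r = −0.72 ± 0.08). The stiffness column is
always derived as E/e′/LASr, never sampled, so the defining identity holds
exactly on every synthetic row.

A calibration note: the pooled Pearson correlation between LASr and the
stiffness index is controlled less by the loadings than by the curvature
of the E/e′/LASr hyperbola. A heavier low-LASr tail in the severe class
makes the relationship more convex and *weakens* r toward −0.72; a
compressed severe cluster linearises it and pushes r past −0.85. The
severe-class LASr spread is therefore the calibration knob, and the
shipped defaults (`default_severity_models()`) were fixed once by
Monte-Carlo search at n = 40 000 against the category-proportion,
correlation and conditional band-occupancy targets, then frozen.

Follow-up is log-normal with meanlog = ln 14 and sdlog = 0.373 — the
two-parameter positive-support family pinned by the reported median of
14 months and quartiles near 11 and 18. Recurrence times are exponential
within risk category, the one-parameter law fixed by a 12-month cumulative
incidence per category: defaults 0.08 / 0.35 / 0.65. The low and high
values sit inside the published "< 10 %" and "> 60 %" bounds; the
intermediate value is nowhere stated and is set to a moderate midpoint.
Censoring is administrative at end of follow-up. A latent recurrence
falling inside the blanking window surfaces as a qualifying episode just
after it, preserving the 12-month incidence while respecting the episode
filter. Nuisance episodes — Poisson(0.5) short episodes of 5–30 s, and
with probability 0.3 one long in-blanking episode — exist only to exercise
the filter; their magnitudes are arbitrary and configurable.

Reproducibility: one root seed; per-patient substreams are derived by
counter (`sample.int` of seed vectors up front), so a cohort is
bit-identical under regeneration and invariant to evaluation order.

**What the generator does not emulate.** Real echo measurements carry
inter-observer variability, non-Gaussian tails, and covariate structure
(age, hypertension, BMI) that the score does not use and the generator
does not model; demographics are deliberately out of scope. Hazards are
constant within category (no early clustering of recurrences after the
blanking period); censoring is purely administrative (no loss to
follow-up). Passing calibration therefore shows the pipeline is correct
and internally consistent under the stated data-generating process — it is
not external validation of the score on patients.

## Survival analysis

`first_recurrence()` operationalizes the recurrence definition: an episode
qualifies when its duration strictly exceeds 30 s and its onset falls
strictly after the 90-day blanking period ("3 months" is operationalized
as 90 days; days convert to months at 30.44 d/month). Strictness is an
argument because the clinical convention is sometimes ≥ 30 s. The event
time is the earliest qualifying onset, otherwise the record is censored at
end of follow-up.

`km_estimate()` is the product-limit estimator written from first
principles, with the Greenwood variance; at tied times events precede
censorings (the standard risk-set convention, stated here because the
source literature is silent). `logrank_test()` is the k-group log-rank
statistic with the hypergeometric variance–covariance, referred to
χ²(k−1); the log-rank is our choice of significance test for stratified
recurrence, as none is named in the source. Both are cross-checked in the
test suite against the `survival` package at 1e-10 tolerance on random
censored datasets — the established implementation serves as oracle only
and is never on the computation path.

`incidence_at(curve, 12)` — the 12-month Kaplan–Meier cumulative
incidence — is how per-category "recurrence rate" is operationalized.
Whether the published per-category rates are 12-month incidences or crude
proportions over variable follow-up is unstated; the report emits both.

## Problem sizes and tolerances

The shipped tests use the sizes at which each property is sharp but cheap:
oracle equivalence of scoring on 1 000 random patients, monotonicity under
10⁴ single-parameter perturbations, KM/log-rank cross-checks on 100 random
censored datasets, hazard recovery at n = 8 000 (within ~2.5 Monte-Carlo
standard errors), and calibrated-cohort checks at n = 10⁴ (proportions
± 3 points, correlation ± 0.08, median follow-up ± 0.5 months).
`scripts/acceptance.R` re-derives the calibration quantities at the same
sizes from a user-supplied seed.

## Known limitations

* The point scheme is a reconstruction; if the score's authors publish
  per-parameter weights, the config — not the code — changes.
* The generator's severity classes are a modeling fiction: real remodeling
  is a continuum, and the three-cluster structure slightly exaggerates
  category separation relative to a continuous latent severity.
* `omit_rescale` makes five-parameter totals comparable to six-parameter
  ones only in expectation; flagged scores should not be mixed silently
  with complete ones in analyses.
* No Cox regression, competing risks or recurrent-event modeling — the
  target claims are stratified first-recurrence curves only.
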
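# easescore

Recurrence after catheter ablation of paroxysmal atrial fibrillation (AF)
is driven largely by how far the left atrium has remodeled — fibrosis,
dilation, conduction slowing and stiffening that standard work-up can miss.
`easescore` implements a six-parameter echocardiographic composite score
(0–12 points) that quantifies this remodeling from routine transthoracic
echo measurements and stratifies patients into low, intermediate and high
recurrence risk, together with everything needed to study such a score
end-to-end without patient data: a calibrated synthetic-cohort generator,
from-scratch Kaplan–Meier / log-rank survival analysis of post-blanking
recurrence, and CSV/YAML tooling with a command-line interface.

It is intended for cardiology researchers and biostatisticians evaluating
composite echo risk scores and for methodologists who need a fully
reproducible, simulation-backed pipeline from measurements to stratified
outcome curves.

## The score

Six parameters, each capturing a different axis of atrial remodeling:

| parameter | meaning | bands (points) |
|---|---|---|
| LASr (%) | reservoir strain — compliance/fibrosis | > 23 (0), 15–23 (1), < 15 (2) |
| PA-TDI (ms) | electromechanical conduction time | < 120 (0), 120–150 (1), > 150 (2) |
| LAVI (mL/m²) | volume index — structural dilation | < 34 (0), 34–48 (1), > 48 (2) |
| E/e′/LASr | stiffness index (derived, never input) | ≤ 0.5 (0), > 0.5 (2) |
| E/e′ | LV filling-pressure surrogate | ≤ 14 (0), > 14 (2) |
| LASct (%) | contractile strain (sinus rhythm only) | > 6 (0), ≤ 6 (2) |

The total T = Σ pᵢ ranges 0–12; categories are low (0–3), intermediate
(4–8), high (9–12). A variant with boundaries 3/7 used in some stratified
presentations ships as `ease_config_fig6()`. Recurrence is defined as an
atrial arrhythmia episode lasting > 30 s with onset after a 90-day
blanking period; arrhythmia-free survival is estimated with the
product-limit estimator S(t) = Π (1 − dᵢ/nᵢ) with Greenwood variance, and
groups are compared with the k-sample log-rank test.

## Worked example

```r
library(easescore)

# one patient: borderline strain, delayed conduction, dilated atrium
compute_breakdown(lasr_pct = 18, pa_tdi_ms = 135, lavi_ml_m2 = 40,
                  e_over_eprime = 10, lasct_pct = 8)
#> EASE score breakdown
#>   lasr      1
#>   patdi     1
#>   lavi      1
#>   stiffness 2
#>   ee        0
#>   lasct     0
#>   stiffness index 0.556
#>   total 5 -> intermediate risk
```

The stiffness index 10/18 ≈ 0.556 exceeds 0.5, adding 2 points to the
three borderline bands; total 5 places the patient in the intermediate
category.

```r
coh <- generate_cohort(generator_params(n = 128, seed = 42))
coh
#> Synthetic ablation cohort: 128 patients (seed 42)
#> category
#>          low intermediate         high
#>           43           60           25
#>   median follow-up 13.4 months; 45 recurrence events

lr <- logrank_test(coh$survival$time, coh$survival$event,
                   coh$survival$category)
#> chisq 30.08 on 2 df, p = 2.94e-07
```

Even at n = 128 the three risk strata separate sharply: recurrence
incidence rises monotonically across categories and the log-rank test is
decisive. `run_report()` renders the same analysis as JSON + markdown.

The CLI wraps the same functions:

```sh
Rscript inst/cli/ease simulate --n 128 --seed 42 --out-dir cohort/
Rscript inst/cli/ease score --in cohort/measurements.csv --out scores.csv
Rscript inst/cli/ease survival --scores scores.csv \
    --episodes cohort/episodes.csv --meta cohort/cohort_meta.csv \
    --blanking-days 90 --min-episode-s 30 --out km.json
Rscript inst/cli/ease report --scores scores.csv \
    --episodes cohort/episodes.csv --meta cohort/cohort_meta.csv --out report
```

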
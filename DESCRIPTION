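Package: easescore
Title: Echocardiographic Atrial Risk Scoring and Recurrence Analysis for
    Atrial Fibrillation Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a six-parameter echocardiographic composite risk
    score (0-12 points) for atrial-fibrillation recurrence after catheter
    ablation, built from left atrial reservoir and contractile strain,
    atrial conduction time (PA-TDI), left atrial volume index, E/e' ratio
    and the derived atrial stiffness index (E/e'/LASr). Provides
    threshold-band configuration with validation, a calibrated synthetic
    patient-cohort generator with correlated echo parameters and
    simulated arrhythmia-episode logs, from-scratch Kaplan-Meier and
    log-rank survival analysis of recurrence under a post-ablation
    blanking period, CSV/YAML input and output, and a command-line
    interface tying scoring, simulation and survival analysis together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
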
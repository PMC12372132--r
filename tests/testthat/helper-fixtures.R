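# Naive scoring oracle: every threshold comparison inlined, independent of
# the band machinery in the package. Default point scheme, Table-1 bounds.
naive_breakdown <- function(lasr, patdi, lavi, ee, lasct) {
  p_lasr <- if (lasr > 23) 0 else if (lasr >= 15) 1 else 2
  p_patdi <- if (patdi < 120) 0 else if (patdi <= 150) 1 else 2
  p_lavi <- if (lavi < 34) 0 else if (lavi <= 48) 1 else 2
  stiff <- ee / lasr
  p_stiff <- if (stiff <= 0.5) 0 else 2
  p_ee <- if (ee <= 14) 0 else 2
  p_lasct <- if (lasct > 6) 0 else 2
  total <- p_lasr + p_patdi + p_lavi + p_stiff + p_ee + p_lasct
  cat <- if (total <= 3) "low" else if (total <= 8) "intermediate" else "high"
  list(points = c(lasr = p_lasr, patdi = p_patdi, lavi = p_lavi,
                  stiffness = p_stiff, ee = p_ee, lasct = p_lasct),
       total = total, category = cat)
}

# random measurement vectors spanning all bands
random_measurements <- function(n, seed) {
  set.seed(seed)
  data.frame(patient_id = sprintf("R%04d", seq_len(n)),
             lasr_pct = runif(n, 3, 40),
             pa_tdi_ms = runif(n, 80, 200),
             lavi_ml_m2 = runif(n, 15, 70),
             e_over_eprime = runif(n, 3, 25),
             lasct_pct = runif(n, 1, 20))
}

# random censored survival datasets for oracle cross-checks
random_survival <- function(n, seed) {
  set.seed(seed)
  # ties on purpose: discretized times
  time <- ceiling(rexp(n, 0.1) * 2) / 2
  event <- runif(n) < 0.6
  data.frame(time = time, event = event)
}
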
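#' Parameters of the synthetic-cohort generator
#'
#' The generator emulates a single-centre cohort of patients undergoing
#' first-time pulmonary vein isolation for paroxysmal atrial fibrillation.
#' Each patient carries a latent remodeling severity (mild / moderate /
#' severe) drawn from `severity_weights`; conditional on severity the five
#' primitive echo parameters are drawn from normal distributions shifted by
#' a single shared latent factor that pushes all parameters jointly toward
#' abnormality, inducing the cross-parameter correlation seen in real
#' atria (in particular the strong negative reservoir-strain vs stiffness
#' relationship). The stiffness index is always derived as E/e'/LASr, never
#' sampled. Follow-up is log-normal with median 14 months and quartiles
#' near 11 and 18. Recurrence times are exponential within risk category,
#' with rates fixed by the 12-month cumulative incidences in
#' `hazard_by_category`; censoring is administrative at end of follow-up.
#' Nuisance episodes (too short, or inside the blanking window) are
#' superimposed so that downstream episode filtering is exercised.
#'
#' @param n cohort size.
#' @param seed integer root seed; per-patient substreams are derived from
#'   it by counter, so cohort content does not depend on generation order.
#' @param severity_weights mixture probabilities for (mild, moderate,
#'   severe) latent remodeling; must sum to 1.
#' @param severity_models named list (`mild`, `moderate`, `severe`) of
#'   per-parameter `c(mean, latent loading, residual sd)` triples for
#'   `lasr`, `patdi`, `lavi`, `ee`, `lasct`; loadings are signed so that a
#'   larger latent factor always means worse (lower strain, higher
#'   conduction time / volume / filling pressure).
#' @param floors physiologic lower clamps applied after sampling.
#' @param followup_meanlog,followup_sdlog log-normal follow-up parameters
#'   (months); defaults `log(14)` and 0.373 reproduce median 14 and
#'   IQR ~ 10.9--18.0.
#' @param hazard_by_category 12-month recurrence probabilities for the
#'   low / intermediate / high categories. Defaults 0.08 / 0.35 / 0.65:
#'   the published bounds are "< 10\%" for low and "> 60\%" for high;
#'   the intermediate value is unstated and set to a moderate midpoint.
#' @param blanking_days post-ablation blanking period, days.
#' @param nuisance_rate expected number of short (5--30 s) episodes per
#'   patient (Poisson).
#' @param inblanking_prob probability of one long episode inside the
#'   blanking window.
#' @param lasct_missing_prob probability that LASct is unmeasurable
#'   (patient in AF at exam); default 0 so the default scoring policy
#'   (`refuse`) never triggers on synthetic data.
#' @return a list of class `generator_params`.
#' @export
generator_params <- function(n = 128,
                             seed = 42,
                             severity_weights = c(mild = 0.30,
                                                  moderate = 0.47,
                                                  severe = 0.23),
                             severity_models = default_severity_models(),
                             floors = c(lasr = 2, patdi = 60, lavi = 10,
                                        ee = 2, lasct = 0.5),
                             followup_meanlog = log(14),
                             followup_sdlog = 0.373,
                             hazard_by_category = c(low = 0.08,
                                                    intermediate = 0.35,
                                                    high = 0.65),
                             blanking_days = 90,
                             nuisance_rate = 0.5,
                             inblanking_prob = 0.3,
                             lasct_missing_prob = 0) {
  p <- structure(as.list(environment()), class = "generator_params")
  stopifnot(abs(sum(p$severity_weights) - 1) < 1e-8,
            all(p$hazard_by_category > 0), all(p$hazard_by_category < 1),
            !is.unsorted(p$hazard_by_category, strictly = TRUE),
            p$followup_sdlog >= 0, p$n >= 1, p$blanking_days >= 0,
            p$lasct_missing_prob >= 0, p$lasct_missing_prob <= 1)
  for (s in c("mild", "moderate", "severe")) {
    m <- p$severity_models[[s]]
    stopifnot(!is.null(m),
              all(c("lasr", "patdi", "lavi", "ee", "lasct") %in% names(m)),
              all(vapply(m, function(x) length(x) == 3 && x[3] >= 0,
                         logical(1))))
  }
  p
}

#' Default severity-conditional parameter models
#'
#' Each entry is `c(mean, latent loading, residual sd)`. Means anchor the
#' classes in the scoring bands (mild patients sit mostly in normal bands,
#' severe mostly in abnormal ones); loadings are negative for the two
#' strain parameters, where abnormality is low values.
#'
#' @return named list over `mild`, `moderate`, `severe`.
#' @export
default_severity_models <- function() {
  list(
    mild = list(lasr  = c(28.5, -2.2, 2.4),
                patdi = c(104, 6.0, 7.5),
                lavi  = c(29, 2.4, 3.2),
                ee    = c(8.0, 0.7, 1.2),
                lasct = c(9.5, -1.4, 1.6)),
    moderate = list(lasr  = c(17.5, -1.3, 1.6),
                    patdi = c(136, 6.0, 7.0),
                    lavi  = c(40.5, 2.6, 3.2),
                    ee    = c(12.7, 0.7, 1.2),
                    lasct = c(7.9, -0.8, 1.2)),
    severe = list(lasr  = c(10.0, -2.4, 2.6),
                  patdi = c(163, 7.0, 8.0),
                  lavi  = c(54, 3.2, 4.0),
                  ee    = c(15.9, 1.4, 1.7),
                  lasct = c(4.8, -1.0, 1.3))
  )
}

#' Draw one patient's echo measurements given latent severity
#'
#' Draws the five primitive parameters from the severity-conditional
#' model: a shared standard-normal latent factor `u` scales every
#' parameter toward abnormality via its loading, independent residual
#' noise is added, and values are clamped at physiologic floors. The
#' stiffness index is derived, never sampled.
#'
#' @param severity `"mild"`, `"moderate"` or `"severe"`.
#' @param params a [generator_params()] object.
#' @return one-row data frame `lasr_pct, pa_tdi_ms, lavi_ml_m2,
#'   e_over_eprime, lasct_pct`. Consumes values from the current RNG
#'   stream; seed externally for reproducibility.
#' @export
sample_measurements <- function(severity, params = generator_params()) {
  m <- params$severity_models[[match.arg(severity,
                                         c("mild", "moderate", "severe"))]]
  u <- stats::rnorm(1)
  draw <- function(tri, floor_val) {
    max(floor_val, tri[1] + tri[2] * u + stats::rnorm(1, sd = tri[3]))
  }
  f <- params$floors
  data.frame(lasr_pct = draw(m$lasr, f[["lasr"]]),
             pa_tdi_ms = draw(m$patdi, f[["patdi"]]),
             lavi_ml_m2 = draw(m$lavi, f[["lavi"]]),
             e_over_eprime = draw(m$ee, f[["ee"]]),
             lasct_pct = draw(m$lasct, f[["lasct"]]))
}

#' Draw one patient's arrhythmia-episode log given risk category
#'
#' A latent recurrence time is drawn from the exponential law whose
#' 12-month cumulative incidence equals the category's entry in
#' `hazard_by_category`. If it falls within follow-up, one qualifying
#' episode (> 30 s, onset after the blanking period) is emitted at that
#' time, shifted to just past the blanking boundary when the latent time
#' falls inside it. Nuisance episodes that the recurrence filter must
#' reject are superimposed: short episodes (5--30 s) at a Poisson rate
#' over follow-up, and with some probability one long episode inside the
#' blanking window. Follow-up shorter than the blanking period therefore
#' yields no qualifying episode regardless of hazard.
#'
#' @param category `"low"`, `"intermediate"` or `"high"`.
#' @param followup_months positive follow-up duration.
#' @param params a [generator_params()].
#' @return data frame `onset_day, duration_s` (possibly zero rows).
#'   Consumes the current RNG stream.
#' @export
sample_outcome <- function(category, followup_months,
                           params = generator_params()) {
  stopifnot(followup_months > 0)
  p12 <- params$hazard_by_category[[match.arg(category,
                                              c("low", "intermediate",
                                                "high"))]]
  rate <- -log(1 - p12) / 12            # per month
  latent_mo <- stats::rexp(1, rate)
  followup_days <- followup_months * DAYS_PER_MONTH

  onset <- numeric(0); dur <- numeric(0)
  if (latent_mo <= followup_months) {
    day <- max(latent_mo * DAYS_PER_MONTH, params$blanking_days + 0.5)
    if (day <= followup_days) {
      onset <- day
      dur <- 31 + stats::rlnorm(1, meanlog = log(180), sdlog = 0.8)
    }
  }
  n_short <- stats::rpois(1, params$nuisance_rate)
  if (n_short > 0) {
    onset <- c(onset, stats::runif(n_short, 1, followup_days))
    dur <- c(dur, stats::runif(n_short, 5, 30))
  }
  if (stats::runif(1) < params$inblanking_prob) {
    day <- stats::runif(1, 1, min(params$blanking_days, followup_days))
    onset <- c(onset, day)
    dur <- c(dur, 31 + stats::rlnorm(1, meanlog = log(180), sdlog = 0.8))
  }
  data.frame(onset_day = onset, duration_s = dur)
}

#' Generate a synthetic patient cohort
#'
#' Draws `params$n` patients: latent severity, echo measurements, score
#' breakdown (via [score_table()] under `config`), log-normal follow-up,
#' and an episode log whose qualifying-recurrence hazard depends on the
#' scored risk category. Per-patient RNG substreams are derived from the
#' root seed by counter, so regeneration with the same parameters is
#' bit-identical and independent of evaluation order.
#'
#' @param params a [generator_params()].
#' @param config threshold configuration used for scoring.
#' @return list of class `ease_cohort` with elements `scores` (the scored
#'   measurement table plus `severity` and `followup_months`), `episodes`
#'   (`patient_id, onset_day, duration_s`), `survival`
#'   (`patient_id, time, event, category` via [build_survival_records()]),
#'   and the `params` used.
#' @examples
#' coh <- generate_cohort(generator_params(n = 50, seed = 1))
#' table(coh$scores$category)
#' @export
generate_cohort <- function(params = generator_params(),
                            config = ease_config()) {
  n <- params$n
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(params$seed)
  seed_meas <- sample.int(.Machine$integer.max, n)
  seed_out <- sample.int(.Machine$integer.max, n)

  sev_levels <- c("mild", "moderate", "severe")
  severity <- character(n)
  meas <- vector("list", n)
  followup <- numeric(n)
  lasct_gone <- logical(n)
  for (i in seq_len(n)) {
    set.seed(seed_meas[i])
    severity[i] <- sample(sev_levels, 1, prob = params$severity_weights)
    meas[[i]] <- sample_measurements(severity[i], params)
    followup[i] <- stats::rlnorm(1, params$followup_meanlog,
                                 params$followup_sdlog)
    lasct_gone[i] <- stats::runif(1) < params$lasct_missing_prob
  }
  measurements <- do.call(rbind, meas)
  measurements <- cbind(patient_id = sprintf("P%04d", seq_len(n)),
                        measurements)
  measurements$lasct_pct[lasct_gone] <- NA_real_

  scores <- score_table(measurements, config)
  scores$severity <- severity
  scores$followup_months <- followup

  eps <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seed_out[i])
    e <- sample_outcome(as.character(scores$category[i]), followup[i],
                        params)
    if (nrow(e))
      eps[[i]] <- cbind(patient_id = scores$patient_id[i], e)
  }
  episodes <- do.call(rbind, eps)
  if (is.null(episodes))
    episodes <- data.frame(patient_id = character(0), onset_day = numeric(0),
                           duration_s = numeric(0))

  surv <- build_survival_records(
    episodes,
    meta = data.frame(patient_id = scores$patient_id,
                      followup_months = followup),
    categories = scores[c("patient_id", "category")],
    blanking_days = params$blanking_days)

  structure(list(scores = scores, episodes = episodes, survival = surv,
                 params = params),
            class = "ease_cohort")
}

#' @export
print.ease_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ablation cohort: %d patients (seed %s)\n",
              nrow(x$scores), format(x$params$seed)))
  print(table(category = x$scores$category))
  cat(sprintf("  median follow-up %.1f months; %d recurrence events\n",
              stats::median(x$scores$followup_months), sum(x$survival$event)))
  invisible(x)
}

#' Calibration report for a synthetic cohort
#'
#' Compares the cohort's empirical behaviour against the targets the
#' generator is calibrated to: risk-category proportions, the Pearson
#' correlation between reservoir strain and the stiffness index, median
#' follow-up, and the per-category 12-month Kaplan-Meier recurrence
#' incidence bounds. Also returns the full pairwise correlation matrix of
#' the six score parameters. Constant columns make a correlation
#' undefined; such entries are flagged rather than propagated as NaN.
#'
#' @param cohort an [generate_cohort()] result.
#' @param targets named list of targets and tolerances; see defaults in
#'   the function signature.
#' @return list with `checks` (data frame: target, value, reference,
#'   tolerance/bound, pass) and `correlations` (6 x 6 matrix, NA where
#'   undefined).
#' @export
calibration_report <- function(cohort,
                               targets = list(
                                 prop_low = c(29.7, 3), prop_intermediate = c(47.7, 3),
                                 prop_high = c(22.6, 3),
                                 cor_lasr_stiffness = c(-0.72, 0.08),
                                 median_followup = c(14, 0.5),
                                 incidence12_low_max = 10,
                                 incidence12_high_min = 60)) {
  stopifnot(inherits(cohort, "ease_cohort"), nrow(cohort$scores) > 0)
  sc <- cohort$scores

  prop <- 100 * prop.table(table(sc$category))
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }
  r <- safe_cor(sc$lasr_pct, sc$stiffness)

  params6 <- sc[c("lasr_pct", "pa_tdi_ms", "lavi_ml_m2", "stiffness",
                  "e_over_eprime", "lasct_pct")]
  cmat <- matrix(NA_real_, 6, 6, dimnames = list(names(params6),
                                                 names(params6)))
  ok <- !vapply(params6, function(col) anyNA(col) || stats::sd(col) == 0,
                logical(1))
  if (any(ok)) cmat[ok, ok] <- stats::cor(params6[ok])

  inc12 <- vapply(c("low", "intermediate", "high"), function(cat) {
    s <- cohort$survival[cohort$survival$category == cat, ]
    if (nrow(s) == 0) return(NA_real_)
    100 * incidence_at(km_estimate(s$time, s$event), 12)
  }, numeric(1))

  med_fu <- stats::median(sc$followup_months)
  row <- function(name, value, ref, tol, pass)
    data.frame(target = name, value = value, reference = ref,
               tolerance = tol, pass = pass)
  checks <- rbind(
    row("prop_low_pct", prop[["low"]], targets$prop_low[1],
        targets$prop_low[2],
        abs(prop[["low"]] - targets$prop_low[1]) <= targets$prop_low[2]),
    row("prop_intermediate_pct", prop[["intermediate"]],
        targets$prop_intermediate[1], targets$prop_intermediate[2],
        abs(prop[["intermediate"]] - targets$prop_intermediate[1]) <=
          targets$prop_intermediate[2]),
    row("prop_high_pct", prop[["high"]], targets$prop_high[1],
        targets$prop_high[2],
        abs(prop[["high"]] - targets$prop_high[1]) <= targets$prop_high[2]),
    row("cor_lasr_stiffness", r, targets$cor_lasr_stiffness[1],
        targets$cor_lasr_stiffness[2],
        !is.na(r) && abs(r - targets$cor_lasr_stiffness[1]) <=
          targets$cor_lasr_stiffness[2]),
    row("median_followup_months", med_fu, targets$median_followup[1],
        targets$median_followup[2],
        abs(med_fu - targets$median_followup[1]) <=
          targets$median_followup[2]),
    row("incidence12_low_pct", inc12[["low"]],
        targets$incidence12_low_max, NA,
        !is.na(inc12[["low"]]) &&
          inc12[["low"]] <= targets$incidence12_low_max),
    row("incidence12_high_pct", inc12[["high"]],
        targets$incidence12_high_min, NA,
        !is.na(inc12[["high"]]) &&
          inc12[["high"]] >= targets$incidence12_high_min))
  if (is.na(r))
    checks$target[checks$target == "cor_lasr_stiffness"] <-
      "cor_lasr_stiffness (undefined: zero variance)"
  list(checks = checks, correlations = cmat,
       incidence12_by_category = inc12)
}
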
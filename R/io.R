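MEASUREMENT_COLS <- c("patient_id", "lasr_pct", "pa_tdi_ms", "lavi_ml_m2",
                      "e_over_eprime", "lasct_pct")

#' Read a patient-measurement CSV
#'
#' Expects a header row with columns `patient_id, lasr_pct, pa_tdi_ms,
#' lavi_ml_m2, e_over_eprime, lasct_pct` (comma-separated, `.` decimal,
#' UTF-8; lines starting with `#` are provenance comments and skipped).
#' An empty `lasct_pct` cell means contractile strain was not measurable.
#' A missing required column is a fatal schema error; malformed or
#' non-positive values are row-level errors collected into an attached
#' report so the remaining rows still parse.
#'
#' @param path CSV file path.
#' @return data frame of valid rows with an attribute `row_errors`, a data
#'   frame (`line`, `patient_id`, `problem`) describing rejected rows.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, comment.char = "#",
                         colClasses = "character",
                         strip.white = TRUE, check.names = TRUE)
  miss <- setdiff(MEASUREMENT_COLS, names(raw))
  if (length(miss))
    stop("measurement file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))

  numeric_cols <- setdiff(MEASUREMENT_COLS, "patient_id")
  errors <- data.frame(line = integer(0), patient_id = character(0),
                       problem = character(0))
  n <- nrow(raw)
  keep <- rep(TRUE, n)
  parsed <- raw[MEASUREMENT_COLS]
  for (col in numeric_cols) {
    txt <- parsed[[col]]
    val <- suppressWarnings(as.numeric(txt))
    blank <- is.na(txt) | txt == ""
    bad_parse <- !blank & is.na(val)
    required <- col != "lasct_pct"
    bad_missing <- if (required) blank else rep(FALSE, n)
    bad_range <- !is.na(val) & val <= 0
    for (w in which(bad_parse))
      errors <- rbind(errors, data.frame(
        line = w + 1L, patient_id = raw$patient_id[w],
        problem = sprintf("%s: not a number ('%s')", col, txt[w])))
    for (w in which(bad_missing))
      errors <- rbind(errors, data.frame(
        line = w + 1L, patient_id = raw$patient_id[w],
        problem = sprintf("%s: required value missing", col)))
    for (w in which(bad_range))
      errors <- rbind(errors, data.frame(
        line = w + 1L, patient_id = raw$patient_id[w],
        problem = sprintf("%s: must be positive (%g)", col, val[w])))
    keep <- keep & !(bad_parse | bad_missing | bad_range)
    parsed[[col]] <- val
  }
  out <- parsed[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(errors))
    warning(nrow(errors), " problem(s) in ", path,
            "; inspect attr(, 'row_errors')")
  attr(out, "row_errors") <- errors
  out
}

#' Write a scored-patient table
#'
#' Deterministic column order (the measurement schema followed by
#' `stiffness`, the six `pts_*` columns, `total`, `category`, `flags`);
#' provenance lines prefixed `#` can carry the seed and configuration
#' hash. Flags are already semicolon-joined strings. The file round-trips
#' through [read_scores()].
#'
#' @param scores a [score_table()] result.
#' @param path output path.
#' @param provenance optional named character vector written as
#'   `# name: value` header lines.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, provenance = NULL) {
  cols <- c(MEASUREMENT_COLS, "stiffness", "pts_lasr", "pts_patdi",
            "pts_lavi", "pts_stiffness", "pts_ee", "pts_lasct", "total",
            "category", "flags")
  miss <- setdiff(cols, names(scores))
  if (length(miss))
    stop("scores table missing column(s): ", paste(miss, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  utils::write.csv(scores[cols], con, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        colClasses = c(patient_id = "character",
                                       flags = "character"))
  df$flags[is.na(df$flags)] <- ""
  df$category <- factor(df$category,
                        levels = c("low", "intermediate", "high"))
  df
}

#' Read an episode log / cohort-metadata CSV
#'
#' `read_episodes()` expects `patient_id, onset_day, duration_s`;
#' `read_cohort_meta()` expects `patient_id, followup_months`.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_episodes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        colClasses = c(patient_id = "character"))
  miss <- setdiff(c("patient_id", "onset_day", "duration_s"), names(df))
  if (length(miss))
    stop("episode file missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_episodes
#' @export
read_cohort_meta <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        colClasses = c(patient_id = "character"))
  miss <- setdiff(c("patient_id", "followup_months"), names(df))
  if (length(miss))
    stop("cohort metadata file missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write a synthetic cohort to a directory
#'
#' Three CSVs: `measurements.csv` (scoring input schema),
#' `episodes.csv` (`patient_id, onset_day, duration_s`) and
#' `cohort_meta.csv` (`patient_id, followup_months, severity`). Each file
#' carries `# seed:` provenance headers.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ease_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prov <- c(seed = format(cohort$params$seed), n = format(cohort$params$n))
  wr <- function(df, name) {
    con <- file(file.path(dir, name), "w")
    on.exit(close(con))
    writeLines(sprintf("# %s: %s", names(prov), prov), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  }
  wr(cohort$scores[MEASUREMENT_COLS], "measurements.csv")
  wr(cohort$episodes, "episodes.csv")
  wr(cohort$scores[c("patient_id", "followup_months", "severity")],
     "cohort_meta.csv")
  invisible(dir)
}

#' Combined analysis report
#'
#' Ties a scored table, a stratified survival analysis and (for synthetic
#' cohorts) a calibration report together into a machine-readable JSON
#' summary and a human-readable markdown rendering: category counts and
#' proportions, per-category 12-month Kaplan-Meier recurrence incidence
#' with Greenwood 95\% confidence intervals, crude recurrence proportions,
#' and the log-rank test across categories (marked not applicable when
#' fewer than two categories are populated).
#'
#' @param scores a [score_table()] result.
#' @param survival_records data frame `patient_id, time, event, category`.
#' @param calibration optional [calibration_report()] result.
#' @param path output path without extension; `<path>.json` and
#'   `<path>.md` are written. `NULL` returns the summary only.
#' @param seed optional provenance seed recorded in the summary.
#' @return the summary list, invisibly when files are written.
#' @export
run_report <- function(scores, survival_records, calibration = NULL,
                       path = NULL, seed = NULL) {
  cats <- c("low", "intermediate", "high")
  counts <- table(factor(scores$category, levels = cats))
  per_cat <- lapply(cats, function(cat) {
    s <- survival_records[survival_records$category == cat, , drop = FALSE]
    if (nrow(s) == 0)
      return(list(n = 0L, events = 0L, incidence12_pct = NA,
                  ci95 = c(NA, NA), crude_pct = NA))
    km <- km_estimate(s$time, s$event)
    inc <- incidence_at(km, 12)
    # Greenwood CI on the survival scale at the last event time <= 12 mo
    idx <- findInterval(12, km$steps$time)
    se <- if (idx >= 1) km$steps$se[idx] else 0
    half <- if (is.na(se)) NA_real_ else 1.96 * se
    list(n = nrow(s), events = sum(s$event),
         incidence12_pct = 100 * inc,
         ci95 = c(max(0, 100 * inc - 100 * half),
                  min(100, 100 * inc + 100 * half)),
         crude_pct = 100 * mean(s$event))
  })
  names(per_cat) <- cats

  populated <- cats[vapply(per_cat, function(x) x$n > 0, logical(1))]
  lr <- if (length(populated) >= 2) {
    s <- survival_records[survival_records$category %in% populated, ]
    logrank_test(s$time, s$event, factor(s$category, levels = populated))
  } else NULL

  summary <- list(
    n = nrow(scores),
    seed = seed,
    category_counts = as.list(stats::setNames(as.integer(counts), cats)),
    category_props_pct = as.list(stats::setNames(
      round(100 * as.integer(counts) / nrow(scores), 2), cats)),
    incidence_12mo = per_cat,
    logrank = if (is.null(lr)) list(applicable = FALSE)
              else list(applicable = TRUE, chisq = lr$chisq, df = lr$df,
                        p_value = lr$p_value),
    calibration = if (is.null(calibration)) NULL else
      lapply(seq_len(nrow(calibration$checks)), function(i)
        as.list(calibration$checks[i, ])))

  if (is.null(path)) return(summary)
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  writeLines(render_report_md(summary), paste0(path, ".md"))
  invisible(summary)
}

render_report_md <- function(s) {
  fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", x))
  lines <- c("# EASE scoring and recurrence report", "",
             sprintf("Patients: %d%s", s$n,
                     if (!is.null(s$seed)) sprintf(" (seed %s)", s$seed)
                     else ""), "",
             "| category | n | % | 12-mo KM incidence % (95% CI) | crude % |",
             "|---|---|---|---|---|")
  for (cat in names(s$incidence_12mo)) {
    pc <- s$incidence_12mo[[cat]]
    ci <- if (anyNA(pc$ci95)) "-" else
      sprintf("%.1f (%.1f-%.1f)", pc$incidence12_pct, pc$ci95[1],
              pc$ci95[2])
    lines <- c(lines, sprintf("| %s | %d | %s | %s | %s |", cat,
                              pc$n, fmt_pct(s$category_props_pct[[cat]]),
                              ci, fmt_pct(pc$crude_pct)))
  }
  lines <- c(lines, "",
             if (isTRUE(s$logrank$applicable))
               sprintf("Log-rank across categories: chi-square %.2f on %d df, p = %.3g",
                       s$logrank$chisq, s$logrank$df, s$logrank$p_value)
             else "Log-rank: not applicable (fewer than two populated categories)")
  if (!is.null(s$calibration)) {
    lines <- c(lines, "", "## Calibration", "",
               "| target | value | reference | pass |", "|---|---|---|---|")
    for (ck in s$calibration)
      lines <- c(lines, sprintf("| %s | %.3f | %s | %s |", ck$target,
                                ck$value, format(ck$reference),
                                if (isTRUE(ck$pass)) "yes" else "NO"))
  }
  lines
}
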
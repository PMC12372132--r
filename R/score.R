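#' Left atrial stiffness index
#'
#' The stiffness index combines an estimate of left ventricular filling
#' pressure (the E/e' ratio) with atrial compliance (reservoir strain,
#' LASr): it is E/e' divided by LASr, with LASr entering as its percent
#' value, so E/e' = 10 with LASr = 20\% gives 0.5 -- exactly the
#' normal/abnormal boundary. Values above 0.5 denote increased left atrial
#' stiffness.
#'
#' @param e_over_eprime E/e' ratio, dimensionless, strictly positive.
#' @param lasr_pct left atrial reservoir strain in percent, strictly
#'   positive.
#' @return `e_over_eprime / lasr_pct`, dimensionless. Vectorized.
#' @examples
#' stiffness_index(10, 20)  # 0.5, the boundary value
#' stiffness_index(12, 30)  # 0.4, normal
#' stiffness_index(14, 10)  # 1.4, markedly stiff
#' @export
stiffness_index <- function(e_over_eprime, lasr_pct) {
  if (any(!is.finite(e_over_eprime)) || any(e_over_eprime <= 0))
    stop("e_over_eprime must be finite and strictly positive")
  if (any(!is.finite(lasr_pct)) || any(lasr_pct <= 0))
    stop("lasr_pct must be finite and strictly positive")
  e_over_eprime / lasr_pct
}

#' Score a single measurement against a parameter's threshold bands
#'
#' Locates the unique band containing `value` and returns its point value.
#' Band edges are resolved by the half-open conventions stored in the band
#' table itself (`lower_inc` / `upper_inc`), so boundary measurements score
#' deterministically.
#'
#' @param value measurement value(s); finite and positive.
#' @param bands a band data frame as held in [ease_config()]
#'   (`config$bands[[param]]`).
#' @return integer point value(s), same length as `value`.
#' @examples
#' cfg <- ease_config()
#' score_parameter(25, cfg$bands$lasr)    # 0: normal reservoir strain
#' score_parameter(18, cfg$bands$lasr)    # 1: borderline
#' score_parameter(50, cfg$bands$lavi)    # 2: severe dilation
#' score_parameter(135, cfg$bands$patdi)  # 1: intermediate conduction delay
#' @export
score_parameter <- function(value, bands) {
  bands <- as_band_frame(bands)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("measurement value must be finite and strictly positive")
  out <- rep(NA_integer_, length(value))
  for (i in seq_len(nrow(bands))) {
    lo_ok <- if (bands$lower_inc[i]) value >= bands$lower[i]
             else value > bands$lower[i]
    hi_ok <- if (bands$upper_inc[i]) value <= bands$upper[i]
             else value < bands$upper[i]
    hit <- lo_ok & hi_ok
    if (any(hit & !is.na(out)))
      stop("overlapping bands: value matched more than one band")
    out[hit] <- bands$points[i]
  }
  if (anyNA(out))
    stop("configuration error: value ", value[which(is.na(out))[1]],
         " falls outside all bands")
  out
}

#' Map a total score to a risk category
#'
#' Totals at or below the first boundary are low risk, totals above the
#' second are high risk, the rest intermediate. With the default boundaries
#' (3 and 8) this reproduces the published interpretation table: 0--3 low,
#' 4--8 intermediate, 9--12 high.
#'
#' @param total integer score(s) in 0..12.
#' @param boundaries integer vector `c(b1, b2)`; defaults to the active
#'   boundaries of [ease_config()].
#' @return factor with levels `low`, `intermediate`, `high`.
#' @examples
#' categorize(c(0, 3, 4, 8, 9, 12))
#' @export
categorize <- function(total, boundaries = c(3L, 8L)) {
  if (any(!is.finite(total)) || any(total < 0) || any(total > 12) ||
      any(total != floor(total)))
    stop("total must be an integer in 0..12")
  lev <- c("low", "intermediate", "high")
  factor(ifelse(total <= boundaries[1], "low",
         ifelse(total <= boundaries[2], "intermediate", "high")),
         levels = lev)
}

#' Score one patient's echocardiographic measurements
#'
#' Applies the per-parameter threshold bands to the six score components --
#' reservoir strain (LASr), atrial conduction time (PA-TDI), volume index
#' (LAVI), the stiffness index (computed internally as E/e'/LASr), the
#' E/e' ratio, and contractile strain (LASct) -- sums the points, and
#' assigns the risk category.
#'
#' LASct is measurable only in sinus rhythm and may be `NA`; what happens
#' then is governed by `config$missing_lasct_policy`:
#' \describe{
#'   \item{refuse}{(default) throw an error rather than silently invent
#'     clinical data;}
#'   \item{worst_case}{assign the maximum 2 points and record a flag;}
#'   \item{omit_rescale}{sum the five available parameters (maximum 10),
#'     rescale to the 0--12 range with half-up rounding, and record a flag.}
#' }
#'
#' @param lasr_pct reservoir strain, percent.
#' @param pa_tdi_ms atrial conduction time, milliseconds.
#' @param lavi_ml_m2 volume index, mL/m^2.
#' @param e_over_eprime E/e' ratio.
#' @param lasct_pct contractile strain, percent, or `NA` if not measurable.
#' @param config an [ease_config()].
#' @return a list of class `ease_breakdown` with elements `points` (named
#'   integer vector over the six parameters; the LASct entry is `NA` when
#'   missing under a non-refuse policy), `stiffness`, `total`, `category`
#'   and `flags` (character vector of data-quality notes).
#' @examples
#' # all-normal patient: total 0, low risk
#' compute_breakdown(28, 100, 30, 8, 10)
#' # mixed patient: stiffness 10/18 = 0.556 is abnormal; total 5
#' compute_breakdown(18, 135, 40, 10, 8)
#' @export
compute_breakdown <- function(lasr_pct, pa_tdi_ms, lavi_ml_m2,
                              e_over_eprime, lasct_pct = NA_real_,
                              config = ease_config()) {
  required <- list(lasr_pct = lasr_pct, pa_tdi_ms = pa_tdi_ms,
                   lavi_ml_m2 = lavi_ml_m2, e_over_eprime = e_over_eprime)
  missing_req <- names(required)[vapply(required, function(x)
    length(x) != 1 || is.na(x), logical(1))]
  if (length(missing_req))
    stop("missing required measurement(s): ",
         paste(missing_req, collapse = ", "))

  stiff <- stiffness_index(e_over_eprime, lasr_pct)
  pts <- c(lasr = score_parameter(lasr_pct, config$bands$lasr),
           patdi = score_parameter(pa_tdi_ms, config$bands$patdi),
           lavi = score_parameter(lavi_ml_m2, config$bands$lavi),
           stiffness = score_parameter(stiff, config$bands$stiffness),
           ee = score_parameter(e_over_eprime, config$bands$ee),
           lasct = NA_integer_)
  flags <- character(0)

  if (length(lasct_pct) == 1 && !is.na(lasct_pct)) {
    pts[["lasct"]] <- score_parameter(lasct_pct, config$bands$lasct)
    total <- sum(pts)
  } else {
    switch(config$missing_lasct_policy,
      refuse = stop("LASct is missing and missing_lasct_policy is 'refuse'"),
      worst_case = {
        pts[["lasct"]] <- max(config$bands$lasct$points)
        total <- sum(pts)
        flags <- c(flags, "lasct_worst_case")
      },
      omit_rescale = {
        avail <- sum(pts, na.rm = TRUE)
        avail_max <- sum(vapply(config$bands[c("lasr", "patdi", "lavi",
                                               "stiffness", "ee")],
                                function(b) max(b$points), numeric(1)))
        # half-up rounding keeps the rescaled total an integer in 0..12
        total <- as.integer(floor(avail * 12 / avail_max + 0.5))
        flags <- c(flags, "lasct_omitted_rescaled")
      })
  }

  structure(list(points = pts,
                 stiffness = stiff,
                 total = as.integer(total),
                 category = categorize(total, config$category_boundaries),
                 flags = flags),
            class = "ease_breakdown")
}

#' @export
print.ease_breakdown <- function(x, ...) {
  cat("EASE score breakdown\n")
  pv <- ifelse(is.na(x$points), "-", as.character(x$points))
  cat(sprintf("  %-9s %s\n", names(x$points), pv), sep = "")
  cat(sprintf("  stiffness index %.3f\n", x$stiffness))
  cat(sprintf("  total %d -> %s risk\n", x$total, as.character(x$category)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Score a table of patients
#'
#' Vectorized scoring of a measurement table as produced by
#' [read_measurements()] or [generate_cohort()]. Column order and naming of
#' the result match the scored-output CSV schema.
#'
#' @param measurements data frame with columns `patient_id`, `lasr_pct`,
#'   `pa_tdi_ms`, `lavi_ml_m2`, `e_over_eprime`, `lasct_pct` (`NA` allowed
#'   in `lasct_pct` only).
#' @param config an [ease_config()].
#' @return the input columns plus `stiffness`, `pts_lasr`, `pts_patdi`,
#'   `pts_lavi`, `pts_stiffness`, `pts_ee`, `pts_lasct`, `total`,
#'   `category`, `flags` (semicolon-joined).
#' @export
score_table <- function(measurements, config = ease_config()) {
  need <- c("patient_id", "lasr_pct", "pa_tdi_ms", "lavi_ml_m2",
            "e_over_eprime", "lasct_pct")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurement table missing column(s): ",
         paste(miss, collapse = ", "))
  m <- measurements
  n <- nrow(m)
  for (col in c("lasr_pct", "pa_tdi_ms", "lavi_ml_m2", "e_over_eprime")) {
    if (anyNA(m[[col]]))
      stop("missing values in required column ", col)
  }

  stiff <- stiffness_index(m$e_over_eprime, m$lasr_pct)
  pts <- data.frame(
    pts_lasr = score_parameter(m$lasr_pct, config$bands$lasr),
    pts_patdi = score_parameter(m$pa_tdi_ms, config$bands$patdi),
    pts_lavi = score_parameter(m$lavi_ml_m2, config$bands$lavi),
    pts_stiffness = score_parameter(stiff, config$bands$stiffness),
    pts_ee = score_parameter(m$e_over_eprime, config$bands$ee),
    pts_lasct = NA_integer_)

  flags <- character(n)
  have_ct <- !is.na(m$lasct_pct)
  if (any(have_ct))
    pts$pts_lasct[have_ct] <- score_parameter(m$lasct_pct[have_ct],
                                              config$bands$lasct)
  total <- integer(n)
  total[have_ct] <- rowSums(pts[have_ct, , drop = FALSE])
  if (any(!have_ct)) {
    switch(config$missing_lasct_policy,
      refuse = stop("LASct missing for ",
                    paste(utils::head(m$patient_id[!have_ct], 5),
                          collapse = ", "),
                    if (sum(!have_ct) > 5) ", ..." else "",
                    " and missing_lasct_policy is 'refuse'"),
      worst_case = {
        pts$pts_lasct[!have_ct] <- max(config$bands$lasct$points)
        total[!have_ct] <- rowSums(pts[!have_ct, , drop = FALSE])
        flags[!have_ct] <- "lasct_worst_case"
      },
      omit_rescale = {
        avail <- rowSums(pts[!have_ct, , drop = FALSE], na.rm = TRUE)
        avail_max <- sum(vapply(config$bands[c("lasr", "patdi", "lavi",
                                               "stiffness", "ee")],
                                function(b) max(b$points), numeric(1)))
        total[!have_ct] <- as.integer(floor(avail * 12 / avail_max + 0.5))
        flags[!have_ct] <- "lasct_omitted_rescaled"
      })
  }

  cbind(m[need], stiffness = stiff, pts,
        data.frame(total = as.integer(total),
                   category = categorize(total, config$category_boundaries),
                   flags = flags))
}
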
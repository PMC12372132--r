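#' Threshold-band scoring configuration
#'
#' An `ease_config` object holds, for each of the six score parameters, an
#' ordered list of half-open bands over the positive measurement axis, each
#' band mapped to a non-negative integer point value, together with the two
#' integer cutpoints that partition the 0--12 total into low / intermediate /
#' high risk categories and the policy applied when contractile strain
#' (LASct) is missing.
#'
#' Bands are stored as a data frame with columns `lower`, `upper`,
#' `lower_inc`, `upper_inc`, `points`. Edges follow the comparatives used to
#' state each threshold: "greater than 23%" makes the normal reservoir-strain
#' band the open interval (23, Inf), leaving [15, 23] borderline and (0, 15)
#' abnormal; "below or equal to 0.5" makes normal stiffness (0, 0.5].
#' Values falling exactly on an edge therefore resolve deterministically.
#'
#' @param category_boundaries integer vector of length 2, `c(b1, b2)` with
#'   `0 <= b1 < b2 <= 12`; totals `<= b1` are low, `(b1, b2]` intermediate,
#'   above `b2` high. Default `c(3, 8)`; the variant `c(3, 7)` used by some
#'   stratified presentations is available via [ease_config_fig6()].
#' @param missing_lasct_policy one of `"refuse"` (error on missing LASct,
#'   the default), `"worst_case"` (assign the maximum 2 points and flag), or
#'   `"omit_rescale"` (score the five available parameters, rescale the
#'   total to the 0--12 range with half-up rounding, and flag).
#' @param bands optional named list of band data frames overriding the
#'   default threshold scheme; names must be a subset of
#'   `c("lasr", "patdi", "lavi", "stiffness", "ee", "lasct")`.
#'
#' @return an object of class `ease_config`.
#'
#' @details The default point scheme gives every parameter a maximum of two
#' points. The three parameters with stated normal / borderline / severe
#' bands (reservoir strain, PA-TDI, volume index) score 0/1/2; the three
#' with a single stated cutpoint (stiffness index, E/e', contractile
#' strain) score 0/2. This is the unique equal-weight assignment whose
#' attainable totals span exactly 0 to 12.
#'
#' @examples
#' cfg <- ease_config()
#' validate_config(cfg)          # character(0): shipped default is valid
#' cfg$bands$lasr                # the three reservoir-strain bands
#' @export
ease_config <- function(category_boundaries = c(3L, 8L),
                        missing_lasct_policy = c("refuse", "worst_case",
                                                 "omit_rescale"),
                        bands = NULL) {
  missing_lasct_policy <- match.arg(missing_lasct_policy)
  b <- default_bands()
  if (!is.null(bands)) {
    stopifnot(is.list(bands))
    bad <- setdiff(names(bands), names(b))
    if (length(bad))
      stop("unknown band parameter(s): ", paste(bad, collapse = ", "))
    for (nm in names(bands)) b[[nm]] <- as_band_frame(bands[[nm]])
  }
  cfg <- structure(list(
    bands = b,
    direction = c(lasr = "low", patdi = "high", lavi = "high",
                  stiffness = "high", ee = "high", lasct = "low"),
    category_boundaries = as.integer(category_boundaries),
    missing_lasct_policy = missing_lasct_policy
  ), class = "ease_config")
  cfg
}

#' @rdname ease_config
#' @export
ease_config_fig6 <- function(missing_lasct_policy = "refuse") {
  ease_config(category_boundaries = c(3L, 7L),
              missing_lasct_policy = missing_lasct_policy)
}

band_frame <- function(lower, upper, lower_inc, upper_inc, points) {
  data.frame(lower = as.numeric(lower), upper = as.numeric(upper),
             lower_inc = as.logical(lower_inc),
             upper_inc = as.logical(upper_inc),
             points = as.integer(points))
}

as_band_frame <- function(x) {
  x <- as.data.frame(x)
  need <- c("lower", "upper", "lower_inc", "upper_inc", "points")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("band table missing column(s): ", paste(miss, collapse = ", "))
  band_frame(x$lower, x$upper, x$lower_inc, x$upper_inc, x$points)
}

# Bands ordered from normal (0 points) outward; the measurement axis is the
# positive reals, so every parameter's bands must tile (0, Inf).
default_bands <- function() {
  list(
    # reservoir strain (%): normal > 23, borderline 15-23, abnormal < 15
    lasr = band_frame(lower = c(23, 15, 0), upper = c(Inf, 23, 15),
                      lower_inc = c(FALSE, TRUE, FALSE),
                      upper_inc = c(FALSE, TRUE, FALSE),
                      points = c(0L, 1L, 2L)),
    # atrial conduction time (ms): normal < 120, abnormal > 150
    patdi = band_frame(lower = c(0, 120, 150), upper = c(120, 150, Inf),
                       lower_inc = c(FALSE, TRUE, FALSE),
                       upper_inc = c(FALSE, TRUE, FALSE),
                       points = c(0L, 1L, 2L)),
    # volume index (mL/m^2): normal < 34, mild-moderate 34-48, severe > 48
    lavi = band_frame(lower = c(0, 34, 48), upper = c(34, 48, Inf),
                      lower_inc = c(FALSE, TRUE, FALSE),
                      upper_inc = c(FALSE, TRUE, FALSE),
                      points = c(0L, 1L, 2L)),
    # stiffness index E/e'/LASr: normal <= 0.5
    stiffness = band_frame(lower = c(0, 0.5), upper = c(0.5, Inf),
                           lower_inc = c(FALSE, FALSE),
                           upper_inc = c(TRUE, FALSE),
                           points = c(0L, 2L)),
    # E/e' ratio: abnormal > 14
    ee = band_frame(lower = c(0, 14), upper = c(14, Inf),
                    lower_inc = c(FALSE, FALSE),
                    upper_inc = c(TRUE, FALSE),
                    points = c(0L, 2L)),
    # contractile strain (%): normal > 6
    lasct = band_frame(lower = c(6, 0), upper = c(Inf, 6),
                       lower_inc = c(FALSE, FALSE),
                       upper_inc = c(FALSE, TRUE),
                       points = c(0L, 2L))
  )
}

#' Validate a threshold configuration
#'
#' Checks band contiguity and coverage of the positive axis, point-value
#' monotonicity in the parameter's abnormality direction, that the maximum
#' attainable total is 12 and the minimum 0, and that the category
#' boundaries are ordered within 0..12. Report-style: returns a character
#' vector of violations, empty when the configuration is valid.
#'
#' @param config an [ease_config()] object.
#' @return character vector of human-readable violations (length 0 = valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  if (!inherits(config, "ease_config"))
    return("not an ease_config object")
  expected <- c("lasr", "patdi", "lavi", "stiffness", "ee", "lasct")
  miss <- setdiff(expected, names(config$bands))
  if (length(miss))
    return(paste0("missing band table(s): ", paste(miss, collapse = ", ")))

  for (nm in expected) {
    b <- config$bands[[nm]]
    o <- order(b$lower)
    bo <- b[o, , drop = FALSE]
    if (bo$lower[1] != 0)
      v <- c(v, sprintf("%s: bands do not cover values near 0", nm))
    if (is.finite(bo$upper[nrow(bo)]))
      v <- c(v, sprintf("%s: bands do not extend to +Inf", nm))
    if (nrow(bo) > 1) {
      for (i in seq_len(nrow(bo) - 1)) {
        if (bo$upper[i] != bo$lower[i + 1]) {
          v <- c(v, sprintf("%s: gap or overlap between %g and %g", nm,
                            bo$upper[i], bo$lower[i + 1]))
        } else if (bo$upper_inc[i] == bo$lower_inc[i + 1]) {
          # shared edge must belong to exactly one band
          v <- c(v, sprintf("%s: edge %g owned by %s bands", nm, bo$upper[i],
                            if (bo$upper_inc[i]) "both" else "neither"))
        }
      }
    }
    if (any(b$points < 0) || any(b$points != floor(b$points)))
      v <- c(v, sprintf("%s: point values must be non-negative integers", nm))
    # monotone with abnormality: ordered by measurement axis, points must be
    # non-increasing ("low" direction: low values abnormal) or non-decreasing
    pts <- bo$points
    mono_ok <- if (config$direction[[nm]] == "low") all(diff(pts) <= 0)
               else all(diff(pts) >= 0)
    if (!mono_ok)
      v <- c(v, sprintf("%s: points not monotone in abnormality direction", nm))
  }

  max_total <- sum(vapply(config$bands[expected],
                          function(b) max(b$points), numeric(1)))
  min_total <- sum(vapply(config$bands[expected],
                          function(b) min(b$points), numeric(1)))
  if (max_total != 12)
    v <- c(v, sprintf("maximum attainable total is %d, not 12", max_total))
  if (min_total != 0)
    v <- c(v, sprintf("minimum attainable total is %d, not 0", min_total))

  cb <- config$category_boundaries
  if (length(cb) != 2 || anyNA(cb) || cb[1] < 0 || cb[2] > 12 ||
      cb[1] >= cb[2])
    v <- c(v, "category boundaries must satisfy 0 <= b1 < b2 <= 12")
  if (!config$missing_lasct_policy %in%
        c("refuse", "worst_case", "omit_rescale"))
    v <- c(v, "unknown missing_lasct_policy")
  v
}

#' @export
print.ease_config <- function(x, ...) {
  cat("EASE threshold configuration\n")
  cb <- x$category_boundaries
  cat(sprintf("  categories: low 0-%d / intermediate %d-%d / high %d-12\n",
              cb[1], cb[1] + 1, cb[2], cb[2] + 1))
  cat("  missing-LASct policy:", x$missing_lasct_policy, "\n")
  for (nm in names(x$bands)) {
    b <- x$bands[[nm]]
    desc <- vapply(seq_len(nrow(b)), function(i) {
      sprintf("%s%g, %g%s -> %d", if (b$lower_inc[i]) "[" else "(",
              b$lower[i], b$upper[i], if (b$upper_inc[i]) "]" else ")",
              b$points[i])
    }, character(1))
    cat(sprintf("  %-9s %s\n", nm, paste(desc, collapse = "  ")))
  }
  invisible(x)
}

#' Read and write threshold configurations as YAML
#'
#' The package ships two configurations under `inst/extdata`:
#' `ease_default.yaml` (category boundaries 3 and 8) and `ease_fig6.yaml`
#' (boundaries 3 and 7).
#'
#' @param path file path.
#' @param config an [ease_config()] object.
#' @return `read_config()` returns an `ease_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  bands <- lapply(y$bands, function(bl) {
    do.call(rbind, lapply(bl, function(r)
      band_frame(r$lower, r$upper, r$lower_inc, r$upper_inc, r$points)))
  })
  cfg <- ease_config(category_boundaries = as.integer(y$category_boundaries),
                     missing_lasct_policy = y$missing_lasct_policy,
                     bands = bands)
  viol <- validate_config(cfg)
  if (length(viol))
    stop("invalid configuration in ", path, ":\n  ",
         paste(viol, collapse = "\n  "))
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ease_config"))
  bands <- lapply(config$bands, function(b)
    lapply(seq_len(nrow(b)), function(i)
      list(lower = b$lower[i], upper = b$upper[i],
           lower_inc = b$lower_inc[i], upper_inc = b$upper_inc[i],
           points = b$points[i])))
  yaml::write_yaml(list(category_boundaries = config$category_boundaries,
                        missing_lasct_policy = config$missing_lasct_policy,
                        bands = bands),
                   path)
  invisible(path)
}
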
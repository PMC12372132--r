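DAYS_PER_MONTH <- 30.44

#' Derive a survival record from an arrhythmia episode log
#'
#' Recurrence after ablation is a documented atrial arrhythmia episode
#' lasting longer than 30 seconds and occurring after a 3-month (90-day)
#' post-ablation blanking period. Episodes inside the blanking window or at
#' or under the duration threshold are nuisance events and do not count.
#' "Longer than" is read strictly (> 30 s), as is "after" the blanking
#' period (onset day > 90); both thresholds and their strictness are
#' arguments. Days convert to months at 30.44 days/month.
#'
#' @param episodes data frame with columns `onset_day` (days since
#'   ablation) and `duration_s` (seconds); zero rows allowed. Episodes with
#'   onset beyond the follow-up horizon are ignored with a warning.
#' @param followup_months administrative censoring time, months.
#' @param blanking_days length of the blanking period, days.
#' @param min_duration_s minimum qualifying episode duration, seconds.
#' @param strict logical; if `TRUE` (default) an episode qualifies only
#'   when strictly exceeding both thresholds.
#' @return a one-row data frame with `time` (months), `event` (logical).
#' @examples
#' eps <- data.frame(onset_day = c(30, 100, 120),
#'                   duration_s = c(45, 25, 60))
#' # day-30 episode is in blanking, day-100 too short: event at day 120
#' first_recurrence(eps, followup_months = 14)
#' @export
first_recurrence <- function(episodes, followup_months,
                             blanking_days = 90, min_duration_s = 30,
                             strict = TRUE) {
  stopifnot(is.numeric(followup_months), length(followup_months) == 1,
            followup_months > 0)
  if (is.null(episodes) || nrow(episodes) == 0)
    return(data.frame(time = followup_months, event = FALSE))
  if (!all(c("onset_day", "duration_s") %in% names(episodes)))
    stop("episodes must have columns onset_day and duration_s")
  if (any(episodes$onset_day <= 0) || any(episodes$duration_s <= 0))
    stop("episode onsets and durations must be positive")

  followup_days <- followup_months * DAYS_PER_MONTH
  beyond <- episodes$onset_day > followup_days
  if (any(beyond)) {
    warning(sum(beyond), " episode(s) with onset beyond follow-up ignored")
    episodes <- episodes[!beyond, , drop = FALSE]
  }
  qual <- if (strict) {
    episodes$duration_s > min_duration_s & episodes$onset_day > blanking_days
  } else {
    episodes$duration_s >= min_duration_s &
      episodes$onset_day >= blanking_days
  }
  if (any(qual)) {
    data.frame(time = min(episodes$onset_day[qual]) / DAYS_PER_MONTH,
               event = TRUE)
  } else {
    data.frame(time = followup_months, event = FALSE)
  }
}

#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric estimate of the arrhythmia-free survival function under
#' right censoring: over the ordered distinct event times t_i with d_i
#' events among n_i subjects at risk, S(t) is the product of (1 - d_i/n_i)
#' for t_i <= t. Subjects censored at an event time are kept in that risk
#' set (events precede censorings at tied times, the standard convention).
#' The Greenwood variance estimate
#' \deqn{\widehat{Var}[S(t)] = S(t)^2 \sum_{t_i \le t} d_i / (n_i (n_i - d_i))}
#' is attached as a standard error at each event time.
#'
#' @param time positive event/censoring times (any unit; months throughout
#'   this package).
#' @param event logical (or 0/1) vector; `TRUE` = event observed, `FALSE` =
#'   censored.
#' @return object of class `km_curve`: a list with `n`, `n_events`, and a
#'   data frame `steps` holding `time` (distinct event times, ascending),
#'   `n_risk`, `n_event`, `surv`, `se` (Greenwood; `NA` once the curve
#'   reaches 0).
#' @examples
#' fit <- km_estimate(c(5, 10, 15, 20, 25),
#'                    c(FALSE, TRUE, TRUE, FALSE, TRUE))
#' fit$steps$surv  # 0.75, 0.50, 0.00
#' @export
km_estimate <- function(time, event) {
  event <- as.logical(event)
  if (length(time) == 0) stop("no survival records supplied")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and positive")
  if (anyNA(event)) stop("event indicator contains NA")

  ev_times <- sort(unique(time[event]))
  n <- length(time)
  if (length(ev_times) == 0) {
    steps <- data.frame(time = numeric(0), n_risk = integer(0),
                        n_event = integer(0), surv = numeric(0),
                        se = numeric(0))
    return(structure(list(n = n, n_events = 0L, steps = steps),
                     class = "km_curve"))
  }
  n_risk <- vapply(ev_times, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ev_times, function(t) sum(event & time == t), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood sum; the terminal d = n term would divide by zero, the
  # variance of an estimate pinned at 0 is reported as NA
  gterm <- ifelse(n_risk > n_event,
                  n_event / (n_risk * (n_risk - n_event)), NA_real_)
  se <- surv * sqrt(cumsum(gterm))
  se[surv == 0] <- NA_real_
  structure(list(n = n, n_events = sum(n_event),
                 steps = data.frame(time = ev_times, n_risk = n_risk,
                                    n_event = n_event, surv = surv,
                                    se = se)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events\n",
              x$n, x$n_events))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cumulative incidence from a Kaplan-Meier curve
#'
#' Returns 1 - S(t) with the survival curve step-interpolated: S is
#' constant between event times, so the value at `t` is taken from the last
#' event time at or before `t`, is 0 before the first event, and extends
#' flat beyond the last.
#'
#' @param curve a [km_estimate()] result.
#' @param t evaluation time(s), >= 0; same unit as the fitted times.
#' @return cumulative incidence in [0, 1], vectorized over `t`.
#' @export
incidence_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t < 0)) stop("t must be non-negative")
  if (nrow(curve$steps) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, curve$steps$time)
  s <- c(1, curve$steps$surv)[idx + 1]
  1 - s
}

#' Multi-group log-rank test
#'
#' Standard k-group log-rank test comparing survival distributions via
#' observed-versus-expected event counts over the pooled distinct event
#' times, with the hypergeometric variance-covariance at each time. The
#' statistic is referred to a chi-square distribution with k - 1 degrees of
#' freedom. For two groups it equals the square of the usual z-form.
#'
#' @param time positive event/censoring times.
#' @param event logical event indicator.
#' @param group group labels (factor, character or integer); every level
#'   present must have at least one subject.
#' @return list with `chisq`, `df`, `p_value`, and per-group `observed` and
#'   `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("log-rank test needs at least two groups")
  if (any(table(group) == 0)) stop("every group must be non-empty")
  if (length(unique(c(length(time), length(event), length(group)))) != 1)
    stop("time, event and group lengths differ")

  ev_times <- sort(unique(time[event]))
  O <- as.numeric(tapply(event, group, sum, default = 0))
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    dj <- sum(event & time == t)
    nij <- as.numeric(tapply(at_risk, group, sum, default = 0))
    E <- E + dj * nij / nj
    if (nj > 1) {
      p <- nij / nj
      V <- V + dj * (nj - dj) / (nj - 1) * (diag(p, k) - outer(p, p))
    }
  }
  d <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chisq <- if (all(abs(d) < 1e-12)) 0 else
    as.numeric(t(d) %*% solve(Vk, d))
  list(chisq = chisq, df = k - 1L,
       p_value = stats::pchisq(chisq, df = k - 1, lower.tail = FALSE),
       observed = stats::setNames(O, levels(group)),
       expected = stats::setNames(E, levels(group)))
}

#' Survival records for a whole cohort
#'
#' Applies [first_recurrence()] patient by patient, joining an episode log
#' to per-patient follow-up durations and risk-category labels.
#'
#' @param episodes data frame `patient_id, onset_day, duration_s` (patients
#'   with no episodes simply do not appear).
#' @param meta data frame `patient_id, followup_months`.
#' @param categories optional data frame `patient_id, category` merged onto
#'   the result.
#' @inheritParams first_recurrence
#' @return data frame `patient_id, time, event` (+ `category`).
#' @export
build_survival_records <- function(episodes, meta, categories = NULL,
                                   blanking_days = 90, min_duration_s = 30,
                                   strict = TRUE) {
  stopifnot(all(c("patient_id", "followup_months") %in% names(meta)))
  ep_split <- if (is.null(episodes) || nrow(episodes) == 0) list()
              else split(episodes, episodes$patient_id)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    pid <- meta$patient_id[i]
    rec <- first_recurrence(ep_split[[as.character(pid)]],
                            meta$followup_months[i],
                            blanking_days = blanking_days,
                            min_duration_s = min_duration_s,
                            strict = strict)
    cbind(patient_id = pid, rec)
  })
  out <- do.call(rbind, recs)
  if (!is.null(categories))
    out <- merge(out, categories[c("patient_id", "category")],
                 by = "patient_id", sort = FALSE)
  out
}
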
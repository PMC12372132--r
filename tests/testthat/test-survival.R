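test_that("recurrence filter applies blanking and duration rules strictly", {
  eps <- data.frame(onset_day = c(30, 100, 120), duration_s = c(45, 25, 60))
  rec <- first_recurrence(eps, followup_months = 14)
  expect_true(rec$event)
  expect_equal(rec$time, 120 / 30.44)   # in-blanking and short episodes drop

  expect_identical(first_recurrence(NULL, 14),
                   data.frame(time = 14, event = FALSE))
  expect_identical(first_recurrence(data.frame(onset_day = numeric(0),
                                               duration_s = numeric(0)), 14),
                   data.frame(time = 14, event = FALSE))

  # both strict inequalities satisfied by the narrowest margin
  rec <- first_recurrence(data.frame(onset_day = 91, duration_s = 31), 14)
  expect_true(rec$event)
  # at the boundary neither qualifies under strict reading
  rec <- first_recurrence(data.frame(onset_day = c(90, 120),
                                     duration_s = c(60, 30)), 14)
  expect_false(rec$event)
  # non-strict mode admits both
  rec <- first_recurrence(data.frame(onset_day = 90, duration_s = 30), 14,
                          strict = FALSE)
  expect_true(rec$event)

  # permutation invariance in episode order
  set.seed(5)
  eps <- data.frame(onset_day = runif(20, 1, 400),
                    duration_s = runif(20, 5, 400))
  r1 <- first_recurrence(eps, 14)
  r2 <- first_recurrence(eps[sample(20), ], 14)
  expect_identical(r1, r2)

  # onset beyond follow-up ignored with a warning
  expect_warning(
    rec <- first_recurrence(data.frame(onset_day = 500, duration_s = 60), 12),
    "beyond follow-up")
  expect_false(rec$event)
})

test_that("product-limit estimator reproduces the hand-computed curve", {
  fit <- km_estimate(c(5, 10, 15, 20, 25),
                     c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(fit$steps$time, c(10, 15, 25))
  expect_equal(fit$steps$n_risk, c(4L, 3L, 1L))
  expect_equal(fit$steps$surv, c(0.75, 0.50, 0))
  # survival starts at 1, non-increasing, in [0, 1]
  expect_true(all(diff(c(1, fit$steps$surv)) <= 0))

  # incidence reads the step function
  expect_equal(incidence_at(fit, 12), 0.25)
  expect_equal(incidence_at(fit, 0), 0)
  expect_equal(incidence_at(fit, 100), 1)

  # all censored: S identically 1
  allc <- km_estimate(c(3, 7, 9), c(FALSE, FALSE, FALSE))
  expect_identical(nrow(allc$steps), 0L)
  expect_equal(incidence_at(allc, 5), 0)

  # single subject with an event: S jumps 1 -> 0
  one <- km_estimate(4, TRUE)
  expect_equal(one$steps$surv, 0)
  expect_equal(incidence_at(one, c(3.9, 4)), c(0, 1))

  expect_error(km_estimate(numeric(0), logical(0)), "no survival records")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(31)
  t <- rexp(200, 0.2)
  fit <- km_estimate(t, rep(TRUE, 200))
  ecdf_surv <- 1 - ecdf(t)(fit$steps$time)
  expect_equal(fit$steps$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("KM curve and Greenwood errors match the survival package", {
  skip_if_not_installed("survival")
  for (k in 1:100) {
    d <- random_survival(n = 20 + (k %% 30), seed = 4000 + k)
    fit <- km_estimate(d$time, d$event)
    ref <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
    at_events <- ref$n.event > 0
    expect_equal(fit$steps$time, ref$time[at_events], tolerance = 1e-12)
    expect_equal(fit$steps$surv, ref$surv[at_events], tolerance = 1e-10)
    expect_equal(fit$steps$n_risk, as.integer(ref$n.risk[at_events]))
    # survfit std.err is on the log scale; Greenwood SE of S is S * that
    se_ref <- ref$surv[at_events] * ref$std.err[at_events]
    pos <- fit$steps$surv > 0
    expect_equal(fit$steps$se[pos], se_ref[pos], tolerance = 1e-10)
  }
})

test_that("log-rank: zero, symmetry and agreement with survdiff", {
  # two identical groups: statistic exactly 0, p = 1
  d <- random_survival(40, seed = 99)
  both <- rbind(d, d)
  g <- rep(c("a", "b"), each = 40)
  res <- logrank_test(both$time, both$event, g)
  expect_equal(res$chisq, 0)
  expect_equal(res$p_value, 1)

  # invariant under permutation of group labels
  set.seed(17)
  d <- random_survival(120, seed = 17)
  g <- sample(c("x", "y", "z"), 120, replace = TRUE)
  r1 <- logrank_test(d$time, d$event, g)
  relabel <- c(x = "z", y = "x", z = "y")
  r2 <- logrank_test(d$time, d$event, relabel[g])
  expect_equal(r1$chisq, r2$chisq, tolerance = 1e-12)
  expect_true(r1$chisq >= 0)

  # k = 2 equals the square of the z-form (O-E over sqrt V)
  d2 <- random_survival(80, seed = 23)
  g2 <- rep(c("a", "b"), 40)
  r <- logrank_test(d2$time, d2$event, g2)
  skip_if_not_installed("survival")
  ref <- survival::survdiff(survival::Surv(d2$time, d2$event) ~ g2)
  expect_equal(r$chisq, ref$chisq, tolerance = 1e-10)
  expect_equal(unname(r$observed), unname(ref$obs), tolerance = 1e-12)
  expect_equal(unname(r$expected), unname(ref$exp), tolerance = 1e-10)

  # 3-group agreement too
  r3 <- logrank_test(d$time, d$event, g)
  ref3 <- survival::survdiff(survival::Surv(d$time, d$event) ~ g)
  expect_equal(r3$chisq, ref3$chisq, tolerance = 1e-10)

  expect_error(logrank_test(d$time, d$event, rep("a", 120)), "two groups")
})

test_that("cohort survival records join episodes, follow-up and category", {
  eps <- data.frame(patient_id = c("p1", "p1", "p3"),
                    onset_day = c(40, 200, 95),
                    duration_s = c(120, 45, 31))
  meta <- data.frame(patient_id = c("p1", "p2", "p3"),
                     followup_months = c(14, 10, 12))
  cats <- data.frame(patient_id = c("p1", "p2", "p3"),
                     category = c("high", "low", "intermediate"))
  recs <- build_survival_records(eps, meta, cats)
  expect_identical(recs$patient_id, c("p1", "p2", "p3"))
  expect_identical(recs$event, c(TRUE, FALSE, TRUE))
  expect_equal(recs$time, c(200 / 30.44, 10, 95 / 30.44))
  expect_identical(recs$category, c("high", "low", "intermediate"))
})
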
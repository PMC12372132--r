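test_that("stiffness index is E/e' over LASr-as-percent", {
  expect_identical(stiffness_index(10, 20), 0.5)  # exact boundary value
  expect_identical(stiffness_index(12, 30), 0.4)
  expect_identical(stiffness_index(14, 10), 1.4)
  # agrees with direct division to full floating precision, vectorized
  set.seed(7)
  ee <- runif(50, 2, 25); lasr <- runif(50, 3, 40)
  expect_identical(stiffness_index(ee, lasr), ee / lasr)
  expect_error(stiffness_index(-1, 20), "e_over_eprime")
  expect_error(stiffness_index(10, 0), "lasr_pct")
})

test_that("per-parameter banding follows the stated thresholds and edges", {
  cfg <- ease_config()
  expect_identical(score_parameter(25, cfg$bands$lasr), 0L)
  expect_identical(score_parameter(18, cfg$bands$lasr), 1L)
  expect_identical(score_parameter(50, cfg$bands$lavi), 2L)
  expect_identical(score_parameter(135, cfg$bands$patdi), 1L)
  # edge resolution: 'greater than 23' puts 23 itself in the borderline band
  expect_identical(score_parameter(23, cfg$bands$lasr), 1L)
  expect_identical(score_parameter(15, cfg$bands$lasr), 1L)
  # 'below or equal to 0.5' keeps 0.5 normal; 14 is a normal E/e'
  expect_identical(score_parameter(0.5, cfg$bands$stiffness), 0L)
  expect_identical(score_parameter(14, cfg$bands$ee), 0L)
  expect_identical(score_parameter(6, cfg$bands$lasct), 2L)
  expect_identical(score_parameter(c(120, 150), cfg$bands$patdi), c(1L, 1L))
  expect_error(score_parameter(-3, cfg$bands$lasr), "positive")
})

test_that("breakdown reproduces hand-scored patients", {
  allnormal <- compute_breakdown(28, 100, 30, 8, 10)
  expect_identical(allnormal$total, 0L)
  expect_identical(as.character(allnormal$category), "low")

  worst <- compute_breakdown(12, 160, 52, 16, 4)
  expect_identical(worst$total, 12L)
  expect_identical(as.character(worst$category), "high")
  expect_equal(worst$stiffness, 16 / 12)

  mixed <- compute_breakdown(18, 135, 40, 10, 8)
  expect_equal(mixed$stiffness, 10 / 18)
  expect_identical(unname(mixed$points),
                   c(1L, 1L, 1L, 2L, 0L, 0L))
  expect_identical(mixed$total, 5L)
  expect_identical(as.character(mixed$category), "intermediate")
  expect_error(compute_breakdown(NA, 100, 30, 8, 10), "lasr_pct")
})

test_that("categorize is a total monotone step function over 0..12", {
  expect_identical(as.character(categorize(c(0, 3, 8, 9))),
                   c("low", "low", "intermediate", "high"))
  cats <- categorize(0:12)
  expect_false(is.unsorted(as.integer(cats)))          # monotone
  expect_false(anyNA(cats))                            # total
  expect_identical(as.character(categorize(8, c(3, 7))), "high")
  expect_error(categorize(13), "0..12")
  expect_error(categorize(2.5), "0..12")
})

test_that("missing-LASct policies behave as documented", {
  expect_error(compute_breakdown(18, 135, 40, 10, NA), "refuse")
  wc <- compute_breakdown(18, 135, 40, 10, NA,
                          config = ease_config(missing_lasct_policy =
                                                 "worst_case"))
  expect_identical(wc$total, 7L)                       # 5 + 2 worst-case
  expect_identical(wc$flags, "lasct_worst_case")
  om <- compute_breakdown(18, 135, 40, 10, NA,
                          config = ease_config(missing_lasct_policy =
                                                 "omit_rescale"))
  expect_identical(om$total, 6L)                       # round(5 * 12/10)
  expect_identical(om$flags, "lasct_omitted_rescaled")
})

test_that("config validation reports constructed defects and passes defaults", {
  expect_length(validate_config(ease_config()), 0)
  expect_length(validate_config(ease_config_fig6()), 0)

  # coverage gap between 15 and 16 in the reservoir-strain bands
  gap <- ease_config()
  gap$bands$lasr$upper[3] <- 15 - 1  # abnormal band now (0, 14)
  gap$bands$lasr$lower[2] <- 16
  v <- validate_config(gap)
  expect_true(any(grepl("gap or overlap", v)))

  # point maxima summing to 9, not 12
  low <- ease_config()
  low$bands$ee$points <- c(0L, 1L)
  low$bands$lasct$points <- c(0L, 0L)
  v <- validate_config(low)
  expect_true(any(grepl("not 12", v)))

  bad_cb <- ease_config()
  bad_cb$category_boundaries <- c(8L, 3L)
  expect_true(any(grepl("boundaries", validate_config(bad_cb))))
})

test_that("breakdown equals the naive inline oracle on random patients", {
  m <- random_measurements(1000, seed = 101)
  cfg <- ease_config()
  tab <- score_table(m, cfg)
  for (i in seq_len(nrow(m))) {
    ref <- naive_breakdown(m$lasr_pct[i], m$pa_tdi_ms[i], m$lavi_ml_m2[i],
                           m$e_over_eprime[i], m$lasct_pct[i])
    expect_identical(tab$total[i], as.integer(ref$total))
    expect_identical(as.character(tab$category[i]), ref$category)
  }
  # scalar path agrees with the vectorized path and is pure (bit-identical)
  b1 <- compute_breakdown(m$lasr_pct[1], m$pa_tdi_ms[1], m$lavi_ml_m2[1],
                          m$e_over_eprime[1], m$lasct_pct[1])
  b2 <- compute_breakdown(m$lasr_pct[1], m$pa_tdi_ms[1], m$lavi_ml_m2[1],
                          m$e_over_eprime[1], m$lasct_pct[1])
  expect_identical(b1, b2)
  expect_identical(b1$total, tab$total[1])
})

test_that("totals are conserved and bounded for random patients", {
  m <- random_measurements(500, seed = 11)
  tab <- score_table(m)
  expect_true(all(tab$total >= 0 & tab$total <= 12))
  pts <- tab[c("pts_lasr", "pts_patdi", "pts_lavi", "pts_stiffness",
               "pts_ee", "pts_lasct")]
  expect_identical(as.integer(rowSums(pts)), tab$total)
})

test_that("worsening any single parameter never decreases the total", {
  set.seed(202)
  n <- 10000
  m <- random_measurements(n, seed = 202)
  base <- score_table(m)
  worse <- m
  # pick one parameter per patient and push it toward abnormality
  which_p <- sample(5, n, replace = TRUE)
  delta <- runif(n, 0.1, 15)
  worse$lasr_pct <- ifelse(which_p == 1, pmax(0.5, m$lasr_pct - delta),
                           m$lasr_pct)
  worse$pa_tdi_ms <- ifelse(which_p == 2, m$pa_tdi_ms + delta, m$pa_tdi_ms)
  worse$lavi_ml_m2 <- ifelse(which_p == 3, m$lavi_ml_m2 + delta,
                             m$lavi_ml_m2)
  worse$e_over_eprime <- ifelse(which_p == 4, m$e_over_eprime + delta,
                                m$e_over_eprime)
  worse$lasct_pct <- ifelse(which_p == 5, pmax(0.5, m$lasct_pct - delta),
                            m$lasct_pct)
  res <- score_table(worse)
  expect_true(all(res$total >= base$total))
  expect_true(all(as.integer(res$category) >= as.integer(base$category)))
})
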
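# trajectory featurization: interpolation, windowed CE, extremes, imputation

test_that("a single observation is carried forward to baseline", {
  cv <- piecewise_linear_curve(series("2003-06-01", 95), "2005-01-01")
  expect_equal(cv$support,
               as.numeric(as.Date(c("2003-06-01", "2005-01-01"))))
  expect_equal(curve_value(cv, as.Date(c("2003-06-01", "2004-02-10",
                                         "2005-01-01"))),
               c(95, 95, 95))
  expect_true(is.na(curve_value(cv, as.Date("2003-05-31"))))
  expect_equal(window_cumulative_exposure(
    cv, as.Date(c("2004-01-01", "2005-01-01"))), 95)
  expect_true(is.na(window_cumulative_exposure(
    cv, as.Date(c("2002-01-01", "2004-01-01")))))
  expect_error(piecewise_linear_curve(series(character(), numeric()),
                                      "2005-01-01"), "empty")
})

test_that("linear segments interpolate exactly", {
  t0 <- as.Date("2001-01-10")
  cv <- piecewise_linear_curve(series(c(t0, t0 + 100), c(90, 110)),
                               "2005-01-01")
  expect_equal(curve_value(cv, t0 + 50), 100)
  # trapezoid mean of a linear ramp over its own span
  cv2 <- piecewise_linear_curve(
    series(c("2002-01-01", "2004-01-01"), c(90, 110)), "2005-01-01")
  expect_equal(window_cumulative_exposure(
    cv2, as.Date(c("2002-01-01", "2004-01-01"))), 100)
})

test_that("same-day duplicates are mean-aggregated before interpolation", {
  cv <- piecewise_linear_curve(
    series(c("2003-06-01", "2003-06-01", "2004-06-01"), c(90, 100, 80)),
    "2005-01-01")
  expect_equal(curve_value(cv, as.Date("2003-06-01")), 95)
  expect_length(cv$x, 3)  # two knots plus the carry-forward knot
})

test_that("windowed CE matches the daily-grid trapezoid oracle", {
  set.seed(42)
  wins <- list(c("2000-01-01", "2002-01-01"),
               c("2002-01-01", "2004-01-01"),
               c("2004-01-01", "2005-01-01"))
  for (i in seq_len(300)) {
    k <- sample(1:8, 1)
    dates <- as.Date("1998-01-01") + sort(sample(0:2500, k))
    vals <- runif(k, 60, 140)
    cv <- piecewise_linear_curve(series(dates, vals), "2005-01-01")
    w <- wins[[sample(3, 1)]]
    got <- window_cumulative_exposure(cv, as.Date(w))
    want <- ce_daily_oracle(dates, vals, w[1], w[2])
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("CE lies within the observed range and ignores collinear knots", {
  set.seed(7)
  for (i in seq_len(100)) {
    k <- sample(2:6, 1)
    dates <- as.Date("1999-06-01") + sort(sample(0:1900, k))
    vals <- runif(k, 70, 130)
    cv <- piecewise_linear_curve(series(dates, vals), "2005-01-01")
    w <- as.Date(c("2000-01-01", "2002-01-01"))
    ce <- window_cumulative_exposure(cv, w)
    if (!is.na(ce)) {
      expect_gte(ce, min(vals) - 1e-9)
      expect_lte(ce, max(vals) + 1e-9)
    }
    # insert a redundant collinear observation mid-segment
    mid <- mean(as.numeric(dates[1:2]))
    midval <- curve_value(cv, mid)
    cv2 <- piecewise_linear_curve(
      series(c(dates, as.Date(mid, origin = "1970-01-01")),
             c(vals, midval)), "2005-01-01")
    ce2 <- window_cumulative_exposure(cv2, w)
    expect_equal(ce2, ce, tolerance = 1e-12)
  }
})

test_that("featurization is equivariant under unit rescaling", {
  dates <- as.Date(c("2000-03-01", "2001-07-01", "2003-02-01", "2004-09-01"))
  vals <- c(92, 104, 99, 101)
  sc <- 10
  w <- as.Date(c("2002-01-01", "2004-01-01"))
  cv1 <- piecewise_linear_curve(series(dates, vals), "2005-01-01")
  cv2 <- piecewise_linear_curve(series(dates, sc * vals), "2005-01-01")
  expect_equal(window_cumulative_exposure(cv2, w),
               sc * window_cumulative_exposure(cv1, w))
  expect_equal(extreme_value(series(dates, sc * vals),
                             as.Date(c("2000-01-01", "2004-12-31"))),
               sc * extreme_value(series(dates, vals),
                                  as.Date(c("2000-01-01", "2004-12-31"))))
  expect_equal(most_recent_before(series(dates, sc * vals), "2005-01-01"),
               sc * most_recent_before(series(dates, vals), "2005-01-01"))
})

test_that("extreme and most-recent rules follow their definitions", {
  per <- as.Date(c("2000-01-01", "2004-12-31"))
  hdl <- series(c("2001-01-01", "2002-01-01", "2003-01-01"), c(52, 43, 61))
  expect_equal(extreme_value(hdl, per, "min"), 43)
  fpg <- series(c("2001-01-01", "2002-01-01", "2003-01-01"), c(92, 104, 99))
  expect_equal(extreme_value(fpg, per, "max"), 104)
  late <- series("2005-06-01", 99)
  expect_true(is.na(extreme_value(late, per, "max")))
  two <- series(c("2003-04-01", "2004-08-01"), c(90, 97))
  expect_equal(most_recent_before(two, "2005-01-01"), 97)
  expect_true(is.na(most_recent_before(late, "2005-01-01")))
})

test_that("zero-length windows are rejected", {
  cv <- piecewise_linear_curve(series("1999-01-01", 95), "2005-01-01")
  expect_error(window_cumulative_exposure(
    cv, as.Date(c("2001-01-01", "2001-01-01"))), "window")
})

test_that("built features agree with the scalar operations", {
  raw <- manual_raw(rbind(
    fpg_rows(1, c("1999-11-01", "2001-02-01", "2003-08-01", "2004-10-01"),
             c(88, 104, 96, 99)),
    data.frame(patient_id = 1, variable = "hdl",
               date = as.Date(c("2001-05-01", "2003-05-01")),
               value = c(52, 43))), n = 1)
  cb <- build_cohort(raw, cohort_spec())
  ft <- build_features(raw, cb$cohort, cohort_spec())
  s <- fpg_rows(1, c("1999-11-01", "2001-02-01", "2003-08-01", "2004-10-01"),
                c(88, 104, 96, 99))
  cv <- piecewise_linear_curve(s, "2005-01-01")
  for (k in 1:3) {
    w <- as.Date(c("2000-01-01", "2002-01-01", "2004-01-01",
                   "2005-01-01"))[k:(k + 1)]
    expect_equal(ft[[paste0("fpg_ce_w", k)]],
                 window_cumulative_exposure(cv, w))
  }
  expect_equal(ft$fpg_baseline, 99)
  expect_equal(ft$fpg_ev, 104)   # extreme restricted to 2000-2004
  expect_equal(ft$hdl_ev, 43)
  expect_identical(ft$fpg_missing, 0L)
  expect_identical(ft$ldl_missing, 1L)
  expect_true(is.na(ft$ldl_baseline))
})

test_that("imputation carries CE forward, then falls back to cohort means", {
  ft <- complete_features(4)
  ft$ldl_ce_w2[1] <- NA; ft$ldl_ce_w3[1] <- NA       # carry-forward case
  ft$tg_ce_w1[2] <- NA                               # backward fill case
  out <- impute_features(ft)
  expect_equal(out$ldl_ce_w2[1], ft$ldl_ce_w1[1])
  expect_equal(out$ldl_ce_w3[1], ft$ldl_ce_w1[1])
  expect_equal(out$tg_ce_w1[2], ft$tg_ce_w2[2])
  expect_identical(out$ldl_missing[1], 0L)

  # a variable absent entirely for one patient: cohort mean + indicator
  ft2 <- complete_features(4)
  for (cl in grep("^hdl_", names(ft2), value = TRUE))
    if (cl != "hdl_missing") ft2[[cl]][3] <- NA
  ft2$hdl_missing[3] <- 1L
  out2 <- impute_features(ft2)
  expect_equal(out2$hdl_baseline[3], mean(ft2$hdl_baseline[-3]))
  expect_equal(out2$hdl_ce_w2[3], mean(ft2$hdl_ce_w2[-3]))
  expect_identical(out2$hdl_missing[3], 1L)
  expect_false(anyNA(out2))

  # no missingness: identity
  ft3 <- complete_features(3)
  out3 <- impute_features(ft3)
  attr(out3, "impute_means") <- NULL
  expect_equal(out3, ft3)
})

test_that("imputation honours supplied means and degenerate columns error", {
  ft <- complete_features(3)
  ft$ldl_baseline[1] <- NA
  means <- attr(impute_features(complete_features(5)), "impute_means")
  out <- impute_features(ft, means = means)
  expect_equal(out$ldl_baseline[1], means[["ldl_baseline"]])

  ft2 <- complete_features(3)
  for (cl in grep("^tg_", names(ft2), value = TRUE))
    if (cl != "tg_missing") ft2[[cl]] <- NA_real_
  expect_error(impute_features(ft2), "tg_")
})

test_that("raw-area mode scales CE by the window length", {
  cv <- piecewise_linear_curve(
    series(c("2000-01-01", "2001-12-31"), c(90, 110)), "2005-01-01")
  w <- as.Date(c("2000-01-01", "2002-01-01"))
  avg <- window_cumulative_exposure(cv, w)
  auc <- window_cumulative_exposure(cv, w, normalize = FALSE)
  expect_equal(auc, avg * as.numeric(diff(w)))

  raw <- manual_raw(fpg_rows(1, c("1999-11-01", "2003-06-01"), c(92, 98)),
                    n = 1)
  cb <- build_cohort(raw, cohort_spec())
  ft_avg <- build_features(raw, cb$cohort, cohort_spec())
  ft_auc <- build_features(raw, cb$cohort, cohort_spec(),
                           ce_normalize = FALSE)
  expect_equal(ft_auc$fpg_ce_w1, ft_avg$fpg_ce_w1 * 731)  # 2000-2001 days
})
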
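# Cox fitting, backwards elimination, Breslow hazard, risk prediction

test_that("variant column sets are nested and always carry demographics", {
  b <- variant_columns("baseline"); ce <- variant_columns("ce")
  ev <- variant_columns("ev"); evce <- variant_columns("evce")
  expect_true(all(b %in% ce) && !setequal(b, ce))
  expect_true(all(b %in% ev) && !setequal(b, ev))
  expect_true(all(ce %in% evce) && all(ev %in% evce))
  for (v in list(b, ce, ev, evce))
    expect_true(all(c("age", "male") %in% v))
  expect_true(all(forced_columns() %in% b))
})

# small survival data generator: exponential hazard h0*exp(beta*x)
sim_surv <- function(n, beta, h0 = 0.1, censor = 8, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, h0 * exp(beta * x))
  data.frame(x = x, time = pmin(t, censor),
             event = as.integer(t <= censor))
}

test_that("fit_cox recovers a known log hazard ratio", {
  d <- sim_surv(5000, beta = 0.5, seed = 3)
  fit <- fit_cox(d["x"], d, "x")
  expect_lt(abs(fit$coef[["x"]] - 0.5), 2 * fit$se[["x"]])
  expect_equal(unname(hazard_ratios(fit)), exp(unname(fit$coef)))
  # agrees with the reference implementation it wraps
  ref <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
})

test_that("JSON persistence round-trips a fit and its hazard ratios", {
  d <- sim_surv(400, beta = 0.3, seed = 9)
  fit <- fit_cox(d["x"], d, "x")
  path <- withr::local_tempfile(fileext = ".json")
  write_cox_fit(fit, path)
  back <- read_cox_fit(path)
  expect_equal(back$coef, fit$coef)
  expect_equal(back$cumhaz, fit$cumhaz)
  expect_equal(hazard_ratios(back), hazard_ratios(fit))
  # per-unit interpretation: a 0.034 coefficient is a ~4% relative hazard
  # increase (1.0346, quoted as 1.04 at printed precision)
  back$coef[["x"]] <- 0.034
  expect_lt(abs(unname(hazard_ratios(back)["x"]) - 1.04), 0.006)
})

test_that("constant covariates collapse to the Nelson-Aalen baseline", {
  d <- sim_surv(300, beta = 0, seed = 5)
  d$z <- 0
  fit <- fit_cox(d[, c("z"), drop = FALSE], d, "z")
  expect_identical(fit$variables, character())
  expect_true("z" %in% fit$dropped)
  # independent Nelson-Aalen: cumsum of d_j / n at risk
  ts <- sort(unique(d$time[d$event == 1]))
  na_est <- cumsum(vapply(ts, function(t) sum(d$event[d$time == t]),
                          numeric(1)) /
                     vapply(ts, function(t) sum(d$time >= t), numeric(1)))
  expect_equal(fit$cumhaz$time, ts)
  expect_equal(fit$cumhaz$hazard, na_est, tolerance = 1e-12)
  # predictions for the baseline patient equal the cumulative hazard
  expect_equal(as.numeric(predict_risk(fit, d[1, "z", drop = FALSE],
                                       horizon = max(d$time) + 1)),
               max(na_est), tolerance = 1e-12)
})

test_that("martingale residuals of a training fit sum to zero", {
  raw <- simulate_cohort(tiny_config(n = 800, seed = 13))
  cb <- build_cohort(raw, cohort_spec())
  ft <- impute_features(build_features(raw, cb$cohort, cohort_spec()))
  for (v in c("baseline", "ce")) {
    fit <- fit_cox(ft, cb$cohort,
                   intersect(variant_columns(v), names(ft)))
    pred <- predict_risk(fit, ft, horizon = max(cb$cohort$time) + 1,
                         followup = cb$cohort$time)
    expect_lt(abs(sum(cb$cohort$event - pred)), 1e-8)
  }
})

test_that("partial likelihoods are nested across the four variants", {
  raw <- simulate_cohort(tiny_config(n = 900, seed = 17))
  cb <- build_cohort(raw, cohort_spec())
  ft <- impute_features(build_features(raw, cb$cohort, cohort_spec()))
  ll <- vapply(c("baseline", "ce", "ev", "evce"), function(v)
    fit_cox(ft, cb$cohort, intersect(variant_columns(v), names(ft)))$loglik,
    numeric(1))
  expect_gte(ll[["ce"]], ll[["baseline"]] - 1e-8)
  expect_gte(ll[["ev"]], ll[["baseline"]] - 1e-8)
  expect_gte(ll[["evce"]], ll[["ce"]] - 1e-8)
  expect_gte(ll[["evce"]], ll[["ev"]] - 1e-8)
})

test_that("affine covariate rescaling leaves predictions invariant", {
  d <- sim_surv(600, beta = 0.4, seed = 21)
  d$y <- rnorm(600, 50, 5)
  fit1 <- fit_cox(d[, c("x", "y")], d, c("x", "y"))
  d2 <- d; d2$y <- d$y / 10
  fit2 <- fit_cox(d2[, c("x", "y")], d2, c("x", "y"))
  expect_equal(fit2$coef[["y"]], fit1$coef[["y"]] * 10, tolerance = 1e-6)
  lp1 <- linear_predictor(fit1, d[, c("x", "y")])
  lp2 <- linear_predictor(fit2, d2[, c("x", "y")])
  expect_equal(lp2, lp1, tolerance = 1e-6)
  expect_equal(fit2$cumhaz$hazard, fit1$cumhaz$hazard, tolerance = 1e-6)
  expect_equal(harrell_concordance(lp2, d$time, d$event),
               harrell_concordance(lp1, d$time, d$event))
})

test_that("predict_risk obeys the proportional-hazards identity", {
  d <- sim_surv(500, beta = 0.5, seed = 8)
  fit <- fit_cox(d["x"], d, "x")
  r0 <- predict_risk(fit, data.frame(x = 0), horizon = 5)
  r1 <- predict_risk(fit, data.frame(x = 1), horizon = 5)
  expect_equal(r1 / r0, unname(exp(fit$coef["x"])), tolerance = 1e-12)
  expect_error(predict_risk(fit, data.frame(x = 0), horizon = -1),
               "horizon")
  # beyond the last event time the hazard is carried forward, flagged
  far <- predict_risk(fit, data.frame(x = 0), horizon = 1e6)
  expect_true(isTRUE(attr(far, "extrapolated")))
  expect_equal(as.numeric(far), max(fit$cumhaz$hazard))
})

test_that("backwards elimination removes noise and keeps signal", {
  d <- sim_surv(2500, beta = 0.8, seed = 30)
  set.seed(31)
  removed <- vapply(seq_len(50), function(i) {
    idx <- sample.int(nrow(d), 400)
    di <- d[idx, ]
    di$noise <- rnorm(400)
    fit <- backwards_eliminate(di[, c("x", "noise")], di,
                               c("x", "noise"), forced = character())
    "noise" %in% attr(fit, "eliminated")
  }, logical(1))
  expect_gte(mean(removed), 0.9)

  # strong signal retained, alpha = 1 keeps everything
  d$noise <- rnorm(nrow(d))
  full <- fit_cox(d[, c("x", "noise")], d, c("x", "noise"))
  be1 <- backwards_eliminate(d[, c("x", "noise")], d, c("x", "noise"),
                             alpha = 1, forced = character())
  expect_identical(be1$variables, full$variables)
  expect_equal(be1$coef, full$coef)
  be <- backwards_eliminate(d[, c("x", "noise")], d, c("x", "noise"),
                            forced = character())
  expect_true("x" %in% be$variables)
})

test_that("forced columns survive elimination regardless of p-value", {
  d <- sim_surv(800, beta = 0.6, seed = 12)
  d$junk <- rnorm(800)
  fit <- backwards_eliminate(d[, c("x", "junk")], d, c("x", "junk"),
                             forced = "junk")
  expect_true("junk" %in% fit$variables)
})

test_that("degenerate inputs raise named errors", {
  d <- sim_surv(50, beta = 0, seed = 2)
  d$event <- 0L
  expect_error(fit_cox(d["x"], d, "x"), "at least 2 events")
  d2 <- sim_surv(200, beta = 0, seed = 2)
  d2$x[1] <- NA
  expect_error(fit_cox(d2["x"], d2, "x"), "missing values")
  # a single covariate that perfectly separates event times
  d3 <- data.frame(x = c(rep(1, 30), rep(0, 30)),
                   time = c(seq(0.1, 3, length.out = 30),
                            seq(10, 40, length.out = 30)),
                   event = c(rep(1, 30), rep(0, 30)))
  expect_error(fit_cox(d3["x"], d3, "x"), "separation")
})
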
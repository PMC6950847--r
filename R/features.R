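# Trajectory featurization: piecewise-linear reconstruction of irregular
# series, windowed cumulative exposure (time-average), extreme values,
# most-recent baseline values, and the imputation rules.

#' Piecewise-linear reconstruction of a measurement series
#'
#' Aggregates same-day duplicates by their mean, interpolates linearly
#' between consecutive observations, and carries the last observation
#' forward (constant) to `baseline_date`. The curve is undefined before the
#' first observation — no back-extrapolation — so its support is
#' `[first observation date, baseline_date]`.
#'
#' @param series data.frame with columns `date`, `value` (one variable's
#'   observations; order irrelevant).
#' @param baseline_date End of the curve's support.
#' @return Object of class `traj_curve`: knots `x` (numeric days), `y`, and
#'   `support`.
#' @export
#' @examples
#' cv <- piecewise_linear_curve(
#'   data.frame(date = as.Date(c("2001-03-01", "2001-06-09")),
#'              value = c(90, 110)),
#'   "2005-01-01")
#' curve_value(cv, as.Date("2001-04-20"))  # midpoint of the segment -> 100
piecewise_linear_curve <- function(series, baseline_date) {
  if (is.null(series) || nrow(series) == 0)
    stop("cannot build a curve from an empty series")
  x <- as_date_num(series$date)
  y <- as.numeric(series$value)
  if (any(!is.finite(y))) stop("series values must be finite")
  agg <- tapply(y, x, mean)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  o <- order(x)
  x <- x[o]; y <- y[o]
  bl <- as_date_num(baseline_date)
  if (x[length(x)] > bl)
    stop("observations after baseline_date are not part of the curve; ",
         "filter the series first")
  if (x[length(x)] < bl) {            # carry the last measurement forward
    x <- c(x, bl)
    y <- c(y, y[length(y)])
  }
  structure(list(x = x, y = y, support = c(x[1], bl)),
            class = "traj_curve")
}

#' Evaluate a trajectory curve
#'
#' @param curve A [piecewise_linear_curve()].
#' @param dates Dates (or numeric days) at which to evaluate.
#' @return Numeric values; `NA` outside the curve's support.
#' @export
curve_value <- function(curve, dates) {
  stopifnot(inherits(curve, "traj_curve"))
  xout <- as_date_num(dates)
  if (length(curve$x) == 1)
    return(ifelse(xout == curve$x, curve$y, NA_real_))
  stats::approx(curve$x, curve$y, xout = xout, method = "linear",
                rule = 1)$y
}

#' @export
print.traj_curve <- function(x, ...) {
  cat(sprintf("Piecewise-linear trajectory: %d knots, support %s .. %s\n",
              length(x$x),
              as.Date(x$support[1], origin = "1970-01-01"),
              as.Date(x$support[2], origin = "1970-01-01")))
  invisible(x)
}

# exact integral of a piecewise-linear curve over [a, b] (numeric days);
# assumes support covers [a, b]
.plc_integral <- function(curve, a, b) {
  x <- curve$x; y <- curve$y
  if (length(x) == 1) return(y * (b - a))
  knots <- sort(unique(c(a, b, x[x > a & x < b])))
  vals <- stats::approx(x, y, xout = knots, rule = 2)$y
  sum(diff(knots) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

#' Windowed cumulative exposure
#'
#' The cumulative exposure of a trajectory over a half-open calendar window
#' is the integral of its piecewise-linear curve across the window divided
#' by the window length — the best estimate of the average daily value in
#' that period, in the variable's native units. If the curve's support does
#' not cover the entire window (first observation after the window starts),
#' the exposure is missing.
#'
#' @param curve A [piecewise_linear_curve()].
#' @param window Length-2 date (or numeric-day) vector `[start, end)`.
#' @param normalize Divide the integral by the window length (default). With
#'   `normalize = FALSE` the raw area under the curve in value-days is
#'   returned.
#' @return Numeric scalar, or `NA` if the window is not covered.
#' @export
#' @examples
#' cv <- piecewise_linear_curve(
#'   data.frame(date = as.Date(c("2000-01-01", "2001-12-31")),
#'              value = c(90, 110)),
#'   "2005-01-01")
#' window_cumulative_exposure(cv, as.Date(c("2000-01-01", "2002-01-01")))
window_cumulative_exposure <- function(curve, window, normalize = TRUE) {
  stopifnot(inherits(curve, "traj_curve"))
  a <- as_date_num(window[1])
  b <- as_date_num(window[2])
  if (b <= a) stop("zero-length or inverted window")
  if (curve$support[1] > a) return(NA_real_)
  int <- .plc_integral(curve, a, min(b, curve$support[2]))
  if (b > curve$support[2])
    stop("window extends past the curve's support (baseline)")
  if (normalize) int / (b - a) else int
}

#' Extreme value over a period
#'
#' Most extreme raw observation in the closed period: the minimum for HDL,
#' the maximum for every other variable.
#'
#' @param series data.frame with `date`, `value`.
#' @param period Length-2 date vector (inclusive bounds).
#' @param direction `"max"` or `"min"`.
#' @return The extreme value, or `NA` if no observation falls in the period.
#' @export
extreme_value <- function(series, period, direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.null(series) || nrow(series) == 0) return(NA_real_)
  d <- as_date_num(series$date)
  a <- as_date_num(period[1]); b <- as_date_num(period[2])
  v <- series$value[d >= a & d <= b]
  if (length(v) == 0) return(NA_real_)
  if (direction == "min") min(v) else max(v)
}

#' Most recent value before baseline
#'
#' @param series data.frame with `date`, `value` (same-day duplicates are
#'   mean-aggregated).
#' @param baseline_date Cutoff; only observations strictly before it count.
#' @return The latest pre-baseline value, or `NA` if none exists.
#' @export
most_recent_before <- function(series, baseline_date) {
  if (is.null(series) || nrow(series) == 0) return(NA_real_)
  bl <- as_date_num(baseline_date)
  d <- as_date_num(series$date)
  keep <- d < bl
  if (!any(keep)) return(NA_real_)
  d <- d[keep]; v <- series$value[keep]
  mean(v[d == max(d)])
}

# ---- vectorized CE over a whole measurement table ----------------------

# per-(patient, variable) windowed CE for all three windows, data.table
# implementation of the same piecewise-linear + carry-forward definition
.ce_table <- function(meas, windows, baseline_date, normalize = TRUE) {
  bl <- as_date_num(baseline_date)
  wb <- as_date_num(windows)
  m <- data.table::as.data.table(meas)
  m[, date := as_date_num(date)]
  m <- m[date < bl]
  m <- m[, .(value = mean(value)), by = .(patient_id, variable, date)]
  data.table::setorder(m, patient_id, variable, date)

  firsts <- m[, .(first_obs = min(date)), by = .(patient_id, variable)]

  # carry-forward knot at baseline
  cf <- m[, .SD[.N], by = .(patient_id, variable)]
  cf <- cf[date < bl][, date := bl]
  knots <- rbind(m, cf)
  data.table::setorder(knots, patient_id, variable, date)
  knots[, `:=`(x1 = date, y1 = value,
               x2 = data.table::shift(date, -1),
               y2 = data.table::shift(value, -1)),
        by = .(patient_id, variable)]
  seg <- knots[!is.na(x2) & x2 > x1]

  res <- vector("list", 3)
  for (k in 1:3) {
    a <- wb[k]; b <- wb[k + 1]
    s <- seg[x2 > a & x1 < b]
    if (nrow(s) > 0) {
      lo <- pmax(s$x1, a); hi <- pmin(s$x2, b)
      slope <- (s$y2 - s$y1) / (s$x2 - s$x1)
      vlo <- s$y1 + slope * (lo - s$x1)
      vhi <- s$y1 + slope * (hi - s$x1)
      s[, seg_int := (hi - lo) * (vlo + vhi) / 2]
      denom <- if (normalize) (b - a) else 1
      ints <- s[, .(ce = sum(seg_int) / denom), by = .(patient_id, variable)]
    } else {
      ints <- data.table::data.table(patient_id = integer(),
                                     variable = character(), ce = numeric())
    }
    ints <- merge(firsts, ints, by = c("patient_id", "variable"),
                  all.x = TRUE)
    ints[first_obs > a, ce := NA_real_]   # support must cover the window
    ints[, wk := k]
    res[[k]] <- ints[, .(patient_id, variable, wk, ce)]
  }
  data.table::rbindlist(res)
}

#' Assemble the predictor table
#'
#' Builds, for every cohort patient, the three predictor sets from the raw
#' records: per-variable baseline value (most recent strictly before
#' baseline), extreme value over the full history span (minimum for HDL,
#' maximum otherwise), cumulative exposure in each of the three history
#' windows, and a per-variable missingness indicator (1 when the variable
#' has no observation at all in `[windows[1], baseline)`); plus age, sex
#' and as-of-baseline diagnosis-category and medication-class indicator
#' flags. No imputation is performed here — see [impute_features()].
#'
#' @param raw Raw record tables (as in [build_cohort()]).
#' @param cohort The `cohort` data.frame from [build_cohort()].
#' @param spec A [cohort_spec()].
#' @param ce_normalize Report cumulative exposure as the time-average
#'   (default) rather than the raw area under the curve in value-days.
#' @return data.frame, one row per cohort patient, with columns
#'   `patient_id`, `age`, `male`, `dx_*`, `med_*`, and per variable `v`:
#'   `v_baseline`, `v_ev`, `v_ce_w1`..`v_ce_w3`, `v_missing`. Missing
#'   entries are `NA`.
#' @export
build_features <- function(raw, cohort, spec = cohort_spec(),
                           ce_normalize = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- cohort$patient_id
  bl <- as_date_num(spec$baseline_date)
  wb <- as_date_num(spec$windows)
  vars <- traj_variables()

  meas <- data.table::as.data.table(raw$measurements)
  meas[, date := as_date_num(date)]
  meas <- meas[patient_id %in% ids]

  pre <- meas[date < bl]
  pre_day <- pre[, .(value = mean(value)),
                 by = .(patient_id, variable, date)]

  # baseline (most recent before baseline, same-day mean aggregated)
  data.table::setorder(pre_day, patient_id, variable, date)
  base_dt <- pre_day[, .SD[.N], by = .(patient_id, variable)]

  # 5-year extreme over [windows[1], baseline)
  hist_obs <- pre[date >= wb[1]]
  ev_dt <- hist_obs[, .(ev = if (variable[1] %in% .min_extreme_vars)
    min(value) else max(value)),
    by = .(patient_id, variable)]

  # windowed cumulative exposures
  ce_dt <- .ce_table(meas, spec$windows, spec$baseline_date,
                     normalize = ce_normalize)

  # missingness: no observation in [windows[1], baseline)
  seen <- hist_obs[, .(seen = TRUE), by = .(patient_id, variable)]

  out <- data.table::data.table(patient_id = ids)
  for (v in vars) {
    bv <- base_dt[variable == v, .(patient_id, value)]
    out[, (paste0(v, "_baseline")) :=
          bv$value[match(ids, bv$patient_id)]]
    evv <- ev_dt[variable == v]
    out[, (paste0(v, "_ev")) := evv$ev[match(ids, evv$patient_id)]]
    for (k in 1:3) {
      cv <- ce_dt[variable == v & wk == k]
      out[, (paste0(v, "_ce_w", k)) := cv$ce[match(ids, cv$patient_id)]]
    }
    sv <- seen[variable == v]
    out[, (paste0(v, "_missing")) :=
          as.integer(!(ids %in% sv$patient_id))]
  }

  # demographics and as-of-baseline diagnosis / medication indicators
  out[, age := cohort$age[match(ids, cohort$patient_id)]]
  out[, male := cohort$male[match(ids, cohort$patient_id)]]
  dx <- data.table::as.data.table(raw$diagnoses)
  dx[, date := as_date_num(date)]
  med <- data.table::as.data.table(raw$medications)
  med[, date := as_date_num(date)]
  dx_map <- c(dx_htn = "hypertension", dx_dyslip = "dyslipidemia",
              dx_ifg = "impaired_fasting_glucose", dx_obesity = "obesity")
  for (nm in names(dx_map)) {
    idsx <- dx[category == dx_map[[nm]] & date < bl, unique(patient_id)]
    out[, (nm) := as.integer(ids %in% idsx)]
  }
  med_map <- c(med_antihtn = "antihypertensive",
               med_antilipemic = "antilipemic")
  for (nm in names(med_map)) {
    idsx <- med[class == med_map[[nm]] & date < bl, unique(patient_id)]
    out[, (nm) := as.integer(ids %in% idsx)]
  }

  front <- c("patient_id", "age", "male", names(dx_map), names(med_map))
  data.table::setcolorder(out, c(front, setdiff(names(out), front)))
  as.data.frame(out)
}

#' Impute the predictor table
#'
#' Applies the imputation rules, in order: (1) per patient and variable, a
#' missing cumulative-exposure window inherits the nearest earlier window's
#' value (carry-forward; when the earliest window itself is missing, the
#' earliest available window is carried backward); (2) cells still missing
#' — variables unobserved for that patient — receive the cohort column mean,
#' with the per-variable missingness indicator (set by [build_features()])
#' marking patients whose variable was entirely unobserved; (3) fasting
#' glucose must be complete after step 1 for every patient (guaranteed by
#' the cohort exclusions; asserted here).
#'
#' @param features Output of [build_features()].
#' @param means Optional named vector of column means to impute with (e.g.
#'   computed on a bootstrap in-bag sample); defaults to the means of the
#'   observed values in `features` itself. The means used are attached as
#'   attribute `impute_means`.
#' @return The completed feature data.frame (no `NA`s), with attribute
#'   `impute_means`.
#' @export
impute_features <- function(features, means = NULL) {
  ft <- data.table::as.data.table(features)
  vars <- traj_variables()

  # step 1: carry-forward across CE windows (backward only for the earliest)
  for (v in vars) {
    w1 <- paste0(v, "_ce_w1"); w2 <- paste0(v, "_ce_w2")
    w3 <- paste0(v, "_ce_w3")
    ft[is.na(get(w2)), (w2) := get(w1)]
    ft[is.na(get(w3)), (w3) := get(w2)]
    ft[is.na(get(w2)), (w2) := get(w3)]   # backward fill
    ft[is.na(get(w1)), (w1) := get(w2)]
  }

  fpg_cols <- paste0("fpg_", c("baseline", "ce_w1", "ce_w2", "ce_w3"))
  bad <- which(rowSums(is.na(ft[, ..fpg_cols])) ==
                 length(fpg_cols))
  if (length(bad) > 0)
    stop("patients with no imputable fasting glucose features remain ",
         "(should have been excluded upstream): ",
         paste(utils::head(ft$patient_id[bad], 10), collapse = ", "))

  # step 2: cohort-mean imputation of remaining cells
  value_cols <- unlist(lapply(vars, function(v)
    paste0(v, c("_baseline", "_ev", "_ce_w1", "_ce_w2", "_ce_w3"))))
  if (is.null(means)) {
    means <- vapply(value_cols, function(cl) {
      x <- ft[[cl]]
      if (all(is.na(x)))
        stop("column '", cl, "' has no observed values cohort-wide; ",
             "its mean is undefined")
      mean(x, na.rm = TRUE)
    }, numeric(1))
  } else {
    missing_cols <- setdiff(value_cols, names(means))
    if (length(missing_cols) > 0)
      stop("supplied means lack columns: ",
           paste(missing_cols, collapse = ", "))
  }
  for (cl in value_cols)
    ft[is.na(get(cl)), (cl) := means[[cl]]]

  out <- as.data.frame(ft)
  attr(out, "impute_means") <- means[value_cols]
  out
}
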
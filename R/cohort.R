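# Cohort construction: eligibility, ordered exclusions with a conservation
# ledger, and survival-outcome derivation.

#' Cohort specification
#'
#' Eligibility, exclusion and outcome-derivation rules for turning raw record
#' tables into an analysis cohort. Defaults encode a baseline of 2005-01-01,
#' adults (18+) with at least one record on each side of baseline, three
#' abutting half-open history windows (2000--2001, 2002--2003, 2004),
#' follow-up through 2015-12-31, and a diabetes-defining fasting glucose
#' threshold of "in excess of 125 mg/dl" (strictly greater).
#'
#' @param baseline_date Prediction baseline.
#' @param min_age Minimum age (years) at baseline.
#' @param windows Four boundary dates of the three half-open history windows
#'   `[w1, w2)`, `[w2, w3)`, `[w3, baseline)`; must abut and end at
#'   `baseline_date`.
#' @param followup_end Administrative end of follow-up.
#' @param fpg_threshold Fasting glucose (mg/dl) strictly above which a
#'   measurement indicates diabetes.
#' @param fpg_exclusion Reading of the "no FPG in the history periods"
#'   exclusion: `"all_windows_empty"` (default — excluded only when every
#'   window lacks FPG) or `"any_window_empty"` (excluded when any window
#'   lacks FPG).
#' @param sensitivity_mode If `TRUE`, additionally require at least one FPG
#'   measurement in every window and at least `min_followup_fpg` FPG
#'   measurements after baseline.
#' @param min_followup_fpg Minimum follow-up FPG count under sensitivity
#'   mode.
#' @return Object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec()
cohort_spec <- function(baseline_date = "2005-01-01",
                        min_age = 18,
                        windows = c("2000-01-01", "2002-01-01",
                                    "2004-01-01", "2005-01-01"),
                        followup_end = "2015-12-31",
                        fpg_threshold = 125,
                        fpg_exclusion = c("all_windows_empty",
                                          "any_window_empty"),
                        sensitivity_mode = FALSE,
                        min_followup_fpg = 5) {
  spec <- list(
    baseline_date = as.Date(baseline_date),
    min_age = min_age,
    windows = as.Date(windows),
    followup_end = as.Date(followup_end),
    fpg_threshold = fpg_threshold,
    fpg_exclusion = match.arg(fpg_exclusion),
    sensitivity_mode = isTRUE(sensitivity_mode),
    min_followup_fpg = min_followup_fpg
  )
  if (length(spec$windows) != 4 ||
      is.unsorted(spec$windows, strictly = TRUE))
    stop("windows must be four strictly increasing dates")
  if (spec$windows[4] != spec$baseline_date)
    stop("history windows must abut and end at baseline_date")
  if (spec$followup_end <= spec$baseline_date)
    stop("followup_end must be after baseline_date")
  class(spec) <- "cohort_spec"
  spec
}

#' Exclusion ledger
#'
#' Records, for one cohort build, the initial patient count, the count
#' failing eligibility (age / records on both sides of baseline), the count
#' removed under each exclusion reason (each patient counted once, under the
#' first matching reason in the applied order), and the final cohort size.
#' The constructor enforces the conservation identity
#' `initial - ineligible - sum(exclusions) = final`.
#'
#' @param initial Number of patients in the raw tables.
#' @param ineligible Count failing the eligibility screen.
#' @param exclusions Named integer vector of per-reason exclusion counts, in
#'   the order applied.
#' @param final Final cohort size.
#' @return Object of class `exclusion_ledger`.
#' @export
#' @examples
#' exclusion_ledger(100, 10, c(preexisting_diabetes = 5, no_fpg = 20,
#'                             suspected_diabetes = 5), 60)
exclusion_ledger <- function(initial, ineligible, exclusions, final) {
  led <- list(initial = as.integer(initial),
              ineligible = as.integer(ineligible),
              exclusions = stats::setNames(as.integer(exclusions),
                                           names(exclusions)),
              final = as.integer(final))
  if (led$initial - led$ineligible - sum(led$exclusions) != led$final)
    stop("ledger does not conserve patients: ", led$initial, " - ",
         led$ineligible, " - ", sum(led$exclusions), " != ", led$final)
  if (any(c(led$initial, led$ineligible, led$exclusions, led$final) < 0))
    stop("ledger counts must be nonnegative")
  class(led) <- "exclusion_ledger"
  led
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Cohort exclusion ledger\n")
  cat(sprintf("  initial patients     %8d\n", x$initial))
  cat(sprintf("  - ineligible         %8d\n", x$ineligible))
  for (nm in names(x$exclusions))
    cat(sprintf("  - %-18s %8d\n", nm, x$exclusions[[nm]]))
  cat(sprintf("  = final cohort       %8d\n", x$final))
  invisible(x)
}

# all record dates per patient (a "visit" = any record of any type)
.record_dates <- function(raw) {
  dd <- data.table::rbindlist(list(
    data.table::data.table(patient_id = raw$measurements$patient_id,
                           date = as_date_num(raw$measurements$date)),
    data.table::data.table(patient_id = raw$diagnoses$patient_id,
                           date = as_date_num(raw$diagnoses$date)),
    data.table::data.table(patient_id = raw$medications$patient_id,
                           date = as_date_num(raw$medications$date))
  ))
  dd
}

#' Build the analysis cohort
#'
#' Applies, in order: an eligibility screen (age at baseline at least
#' `spec$min_age`, at least one record strictly before and one strictly
#' after baseline), then the three exclusions — (1) a diabetes diagnosis
#' code before baseline, (2) missing fasting glucose in the history windows
#' (reading per `spec$fpg_exclusion`, strengthened under sensitivity mode),
#' (3) suspected diabetes: any antidiabetic medication record or any single
#' FPG above `spec$fpg_threshold` before baseline. Each excluded patient is
#' counted once, under the first matching reason in `exclusion_order`;
#' permuting the order changes per-reason counts but never final membership.
#' Survival outcomes for the retained patients come from [derive_outcome()].
#'
#' @param raw A `raw_cohort` (from [simulate_cohort()] /
#'   [read_cohort_csv()]) or plain list with the four record tables.
#' @param spec A [cohort_spec()].
#' @param exclusion_order Permutation of `c("preexisting_diabetes",
#'   "no_fpg", "suspected_diabetes")` giving the reason-assignment order.
#' @return List with `cohort` (data.frame: patient_id, age, male, time,
#'   event) and `ledger` (an [exclusion_ledger()]).
#' @export
#' @examples
#' raw <- simulate_cohort(sim_config(n_patients = 200, seed = 3))
#' cb <- build_cohort(raw, cohort_spec())
#' cb$ledger
build_cohort <- function(raw, spec = cohort_spec(),
                         exclusion_order = c("preexisting_diabetes",
                                             "no_fpg",
                                             "suspected_diabetes")) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!setequal(exclusion_order,
                c("preexisting_diabetes", "no_fpg", "suspected_diabetes")))
    stop("exclusion_order must permute the three exclusion reasons")
  demo <- raw$demographics
  if (is.null(demo) || nrow(demo) == 0) stop("empty demographics table")
  if (nrow(raw$measurements) == 0) stop("empty measurements table")

  other_ids <- unique(c(raw$measurements$patient_id,
                        raw$diagnoses$patient_id,
                        raw$medications$patient_id))
  orphans <- setdiff(other_ids, demo$patient_id)
  if (length(orphans) > 0)
    stop("records reference patients missing from demographics: ",
         paste(utils::head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) ", ..." else "")

  bl <- as_date_num(spec$baseline_date)
  rec <- .record_dates(raw)
  pre_post <- rec[, .(pre = any(date < bl), post = any(date > bl)),
                  by = patient_id]
  age <- years_between(demo$birth_date, spec$baseline_date)
  elig_dt <- data.table::data.table(patient_id = demo$patient_id, age = age)
  elig_dt <- merge(elig_dt, pre_post, by = "patient_id", all.x = TRUE)
  elig_dt[is.na(pre), pre := FALSE]
  elig_dt[is.na(post), post := FALSE]
  eligible <- elig_dt[age >= spec$min_age & pre & post, patient_id]
  n_initial <- nrow(demo)
  n_inelig <- n_initial - length(eligible)

  meas <- data.table::as.data.table(raw$measurements)
  meas[, date := as_date_num(date)]
  dx <- data.table::as.data.table(raw$diagnoses)
  dx[, date := as_date_num(date)]
  med <- data.table::as.data.table(raw$medications)
  med[, date := as_date_num(date)]

  # per-reason flags over eligible patients
  pre_dm_ids <- dx[category == "diabetes" & date <= bl, unique(patient_id)]

  wb <- as_date_num(spec$windows)
  fpg <- meas[variable == "fpg"]
  fpg_pre <- fpg[date >= wb[1] & date < wb[4]]
  fpg_pre[, w := findInterval(date, wb)]
  cnt <- data.table::dcast(fpg_pre[, .N, by = .(patient_id, w)],
                           patient_id ~ w, value.var = "N", fill = 0L)
  for (k in c("1", "2", "3"))
    if (!k %in% names(cnt)) cnt[, (k) := 0L]
  if (spec$sensitivity_mode || spec$fpg_exclusion == "any_window_empty") {
    bad_fpg_ids <- union(
      setdiff(elig_dt$patient_id,
              cnt[cnt[["1"]] > 0 & cnt[["2"]] > 0 & cnt[["3"]] > 0,
                  patient_id]),
      if (spec$sensitivity_mode) {
        fu_cnt <- fpg[date > bl, .N, by = patient_id]
        setdiff(elig_dt$patient_id,
                fu_cnt[N >= spec$min_followup_fpg, patient_id])
      } else integer()
    )
  } else {
    bad_fpg_ids <- setdiff(elig_dt$patient_id, cnt$patient_id)
  }

  # records dated exactly on the baseline day count as pre-baseline here:
  # a diabetes indication on the baseline day is prevalent, not incident
  susp_ids <- union(
    med[class == "antidiabetic" & date <= bl, unique(patient_id)],
    fpg[date <= bl & value > spec$fpg_threshold, unique(patient_id)]
  )

  flags <- list(preexisting_diabetes = pre_dm_ids,
                no_fpg = bad_fpg_ids,
                suspected_diabetes = susp_ids)

  remaining <- eligible
  counts <- stats::setNames(integer(length(exclusion_order)),
                            exclusion_order)
  for (reason in exclusion_order) {
    hit <- intersect(remaining, flags[[reason]])
    counts[[reason]] <- length(hit)
    remaining <- setdiff(remaining, hit)
  }

  ledger <- exclusion_ledger(n_initial, n_inelig, counts, length(remaining))

  out <- derive_outcome(raw, remaining, spec)
  cohort <- data.frame(
    patient_id = remaining,
    age = age[match(remaining, demo$patient_id)],
    male = as.integer(demo$sex[match(remaining, demo$patient_id)] == "M"),
    stringsAsFactors = FALSE
  )
  cohort <- merge(cohort, out, by = "patient_id", sort = TRUE)
  list(cohort = cohort, ledger = ledger)
}

#' Derive survival outcomes
#'
#' For each listed patient: the event time is the earliest strictly
#' post-baseline qualifying record — a diabetes diagnosis code or a fasting glucose above
#' `spec$fpg_threshold` — and the censoring time is the earlier of the last
#' record date and `spec$followup_end`. `event = 1` iff a qualifying record
#' precedes (or coincides with) censoring. Times are years from baseline
#' (365.25 days/year).
#'
#' @param raw Raw record tables (as in [build_cohort()]).
#' @param ids Patient ids to derive outcomes for (must have passed the
#'   cohort screen: a qualifying record dated on/before baseline is an
#'   internal-consistency error).
#' @param spec A [cohort_spec()].
#' @return data.frame with `patient_id`, `time` (years, > 0), `event` (0/1).
#' @export
derive_outcome <- function(raw, ids, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  bl <- as_date_num(spec$baseline_date)
  fe <- as_date_num(spec$followup_end)

  dx <- data.table::as.data.table(raw$diagnoses)
  dx[, date := as_date_num(date)]
  meas <- data.table::as.data.table(raw$measurements)
  meas[, date := as_date_num(date)]

  qual <- rbind(
    dx[category == "diabetes" & patient_id %in% ids,
       .(patient_id, date)],
    meas[variable == "fpg" & value > spec$fpg_threshold &
           patient_id %in% ids, .(patient_id, date)]
  )
  if (nrow(qual) > 0 && any(qual$date <= bl)) {
    bad <- unique(qual[date <= bl, patient_id])
    stop("internal consistency: qualifying record on/before baseline for ",
         "patient(s) ", paste(utils::head(bad, 10), collapse = ", "),
         " — these should have been excluded")
  }
  ev <- if (nrow(qual) > 0)
    qual[, .(event_date = min(date)), by = patient_id]
  else data.table::data.table(patient_id = integer(),
                              event_date = numeric())

  rec <- .record_dates(raw)
  last <- rec[patient_id %in% ids, .(last_date = max(date)),
              by = patient_id]

  out <- merge(data.table::data.table(patient_id = ids), last,
               by = "patient_id", all.x = TRUE)
  out <- merge(out, ev, by = "patient_id", all.x = TRUE)
  out[, censor_date := pmin(last_date, fe)]
  out[, event := as.integer(!is.na(event_date) & event_date <= censor_date)]
  out[, end_date := ifelse(event == 1, pmin(event_date, censor_date),
                           censor_date)]
  out[, time := (end_date - bl) / .DAYS_PER_YEAR]
  if (any(out$time <= 0))
    stop("nonpositive follow-up time for patient(s) ",
         paste(utils::head(out[time <= 0, patient_id], 10), collapse = ", "))
  as.data.frame(out[, .(patient_id, time, event)])
}
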
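# Episodic-prediabetes subpopulations: per-window glycemic status, labels,
# and per-group predicted-vs-observed incident reports.

#' Per-window glycemic status and subpopulation labels
#'
#' A history window is `"p"` (prediabetic) when at least one raw fasting
#' glucose in it lies in the prediabetic range 100--125 mg/dl (inclusive),
#' `"n"` (normal) when it has measurements but none in that range, and
#' inherits the previous window's status when it has no measurement (a
#' first window without data is `"n"`). Values above 125 mg/dl before
#' baseline are an internal-consistency error — such patients are excluded
#' upstream.
#'
#' With `source = "ce"` the status is instead derived from the windowed
#' cumulative-exposure averages of an (unimputed) feature table: a window is
#' prediabetic when its FPG time-average lies in 100--125 mg/dl, and
#' windows whose exposure is missing inherit the previous status as above.
#'
#' @param measurements Measurement table (`patient_id`, `variable`, `date`,
#'   `value`).
#' @param ids Cohort patient ids to classify.
#' @param spec A [cohort_spec()] (supplies the windows and threshold).
#' @param source Classify from raw `"measurements"` (default) or from the
#'   `"ce"` averages of `features`.
#' @param features Unimputed [build_features()] table; required for
#'   `source = "ce"`.
#' @return data.frame with `patient_id`, `w1`, `w2`, `w3` (each `"n"` or
#'   `"p"`) and `label` (see [assign_subpopulation()]).
#' @export
classify_windows <- function(measurements, ids, spec = cohort_spec(),
                             source = c("measurements", "ce"),
                             features = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  source <- match.arg(source)
  if (source == "ce") {
    if (is.null(features))
      stop("source = 'ce' needs the unimputed feature table")
    fr <- features[match(ids, features$patient_id), ]
    out <- data.frame(patient_id = ids, w1 = NA_character_,
                      w2 = NA_character_, w3 = NA_character_,
                      stringsAsFactors = FALSE)
    for (k in 1:3) {
      ce <- fr[[paste0("fpg_ce_w", k)]]
      out[[paste0("w", k)]] <-
        ifelse(is.na(ce), NA_character_,
               ifelse(ce >= 100 & ce <= spec$fpg_threshold, "p", "n"))
    }
    out$w1[is.na(out$w1)] <- "n"
    out$w2[is.na(out$w2)] <- out$w1[is.na(out$w2)]
    out$w3[is.na(out$w3)] <- out$w2[is.na(out$w3)]
    out$label <- apply(out[, c("w1", "w2", "w3")], 1, assign_subpopulation)
    return(out)
  }
  wb <- as_date_num(spec$windows)
  fpg <- data.table::as.data.table(measurements)
  fpg <- fpg[variable == "fpg" & patient_id %in% ids]
  fpg[, date := as_date_num(date)]
  fpg <- fpg[date >= wb[1] & date < wb[4]]
  if (nrow(fpg) > 0 && any(fpg$value > spec$fpg_threshold))
    stop("internal consistency: pre-baseline FPG above ",
         spec$fpg_threshold, " mg/dl for patient(s) ",
         paste(utils::head(fpg[value > spec$fpg_threshold,
                               unique(patient_id)], 10), collapse = ", "))
  fpg[, w := findInterval(date, wb)]
  st <- fpg[, .(status = ifelse(any(value >= 100 & value <= 125),
                                "p", "n")),
            by = .(patient_id, w)]

  out <- data.frame(patient_id = ids, w1 = NA_character_,
                    w2 = NA_character_, w3 = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in 1:3) {
    sk <- st[w == k]
    out[[paste0("w", k)]] <- sk$status[match(ids, sk$patient_id)]
  }
  # no measurement: carry status from the previous window; first window "n"
  out$w1[is.na(out$w1)] <- "n"
  out$w2[is.na(out$w2)] <- out$w1[is.na(out$w2)]
  out$w3[is.na(out$w3)] <- out$w2[is.na(out$w3)]
  out$label <- apply(out[, c("w1", "w2", "w3")], 1, assign_subpopulation)
  out
}

#' Map a status triple to a subpopulation label
#'
#' `(p,n,n) -> "pnn"`, `(n,p,n) -> "npn"`, `(n,n,p) -> "nnp"`,
#' `(n,p,p) -> "npp"`, `(n,n,n) -> "nnn"`; any other pattern (for example
#' `p,p,*`) is `"other"`.
#'
#' @param statuses Character vector of three `"n"`/`"p"` window statuses.
#' @return One of `"pnn"`, `"npn"`, `"nnp"`, `"npp"`, `"nnn"`, `"other"`.
#' @export
#' @examples
#' assign_subpopulation(c("p", "n", "n"))
assign_subpopulation <- function(statuses) {
  stopifnot(length(statuses) == 3, all(statuses %in% c("n", "p")))
  pat <- paste(statuses, collapse = "")
  if (pat %in% c("pnn", "npn", "nnp", "npp", "nnn")) pat else "other"
}

#' Subpopulation labels in reporting order
#' @return Character vector of the six labels.
#' @export
subpopulation_labels <- function() {
  c("pnn", "npn", "nnp", "npp", "nnn", "other")
}

#' Per-subpopulation risk report
#'
#' For each patient, `Pred` is the model's expected number of incident
#' events over `min(horizon, own follow-up)` years ([predict_risk()]) and
#' `observed` is the event indicator within that horizon. Each group then
#' reports its size, mean `Pred`, mean `observed`, and
#' `error = mean(Pred - observed)` — the signed difference between
#' estimated and observed incidents, i.e. the negative of the conventional
#' martingale residual. Fits are expected to come from the full cohort;
#' under the training fit the error over the whole cohort is zero by the
#' Breslow calibration identity.
#'
#' @param features Imputed feature table.
#' @param outcomes data.frame with `time`, `event` aligned with `features`.
#' @param labels `label` column (or the data.frame) from
#'   [classify_windows()], aligned with `features` rows.
#' @param fits Named list of [fit_cox()] objects (one per model variant).
#' @param horizon Horizon in years (default 10).
#' @return Object of class `subpop_report`: data.frame with `group`,
#'   `model`, `n`, `pred`, `observed`, `error`; empty groups keep `n = 0`
#'   with `NA` means.
#' @export
group_risk_report <- function(features, outcomes, labels, fits,
                              horizon = 10) {
  if (is.data.frame(labels)) labels <- labels$label
  stopifnot(length(labels) == nrow(features),
            nrow(features) == nrow(outcomes))
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("fits must be a named list of cox_fit objects")
  obs <- as.integer(outcomes$event == 1 & outcomes$time <= horizon)
  groups <- subpopulation_labels()
  rows <- list()
  for (m in names(fits)) {
    pred <- predict_risk(fits[[m]], features, horizon,
                         followup = outcomes$time)
    for (g in groups) {
      sel <- labels == g
      rows[[paste(m, g)]] <- data.frame(
        group = g, model = m, n = sum(sel),
        pred = if (any(sel)) mean(pred[sel]) else NA_real_,
        observed = if (any(sel)) mean(obs[sel]) else NA_real_,
        error = if (any(sel)) mean(pred[sel] - obs[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("subpop_report", "data.frame")
  out
}

#' @export
print.subpop_report <- function(x, ...) {
  cat("Subpopulation risk report (Pred = expected incidents; ",
      "error = mean(Pred - observed))\n", sep = "")
  df <- as.data.frame(x)
  df$pred <- round(df$pred, 3)
  df$observed <- round(df$observed, 3)
  df$error <- round(df$error, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
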
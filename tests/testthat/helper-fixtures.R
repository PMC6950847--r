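# shared fixture builders for the test suite (all data generated in code)

# a measurement series data.frame
series <- function(dates, values) {
  data.frame(date = as.Date(dates), value = values)
}

# minimal simulation config for fast unit tests
tiny_config <- function(n = 50, seed = 1, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

# config for clean archetype identification: dense, precise FPG sampling,
# no structural noise sources
pure_config <- function(n, seed, mix, ...) {
  sim_config(
    n_patients = n, seed = seed,
    archetype_mix = mix,
    visit_rate = 6,
    measure_prob = c(fpg = 0.9, bmi = 0.9, sbp = 0.5, dbp = 0.5,
                     ldl = 0.3, hdl = 0.3, tg = 0.3),
    noise_sd = c(fpg = 1, bmi = 0.3, sbp = 8, dbp = 5, ldl = 12,
                 hdl = 5, tg = 25),
    dropout_rate = 0, ineligible_frac = 0, prevalent_dm_frac = 0,
    antidiabetic_frac = 0, ...)
}

# hand-built raw record tables around the default 2005-01-01 baseline;
# each patient gets an eligibility-satisfying bmi record on both sides
manual_raw <- function(measurements = NULL, diagnoses = NULL,
                       medications = NULL, n = 3) {
  pid <- seq_len(n)
  demo <- data.frame(patient_id = pid,
                     birth_date = as.Date("1960-06-15"),
                     sex = rep(c("M", "F"), length.out = n),
                     stringsAsFactors = FALSE)
  anchor <- do.call(rbind, lapply(pid, function(p) {
    data.frame(patient_id = p, variable = "bmi",
               date = as.Date(c("2001-03-01", "2010-03-01")),
               value = 27, stringsAsFactors = FALSE)
  }))
  meas <- rbind(anchor, measurements)
  dx <- if (is.null(diagnoses))
    data.frame(patient_id = integer(), category = character(),
               date = as.Date(character()), stringsAsFactors = FALSE)
  else diagnoses
  med <- if (is.null(medications))
    data.frame(patient_id = integer(), class = character(),
               date = as.Date(character()), stringsAsFactors = FALSE)
  else medications
  structure(list(demographics = demo, measurements = meas,
                 diagnoses = dx, medications = med, latent = NULL,
                 config = NULL),
            class = "raw_cohort")
}

# fpg rows helper
fpg_rows <- function(pid, dates, values) {
  data.frame(patient_id = pid, variable = "fpg", date = as.Date(dates),
             value = values, stringsAsFactors = FALSE)
}

# a complete one-row-per-patient feature table with every pipeline column,
# all values observed; tests poke NAs into it to exercise imputation
complete_features <- function(n = 4) {
  vars <- traj_variables()
  out <- data.frame(patient_id = seq_len(n), age = 50, male = 1,
                    dx_htn = 0, dx_dyslip = 0, dx_ifg = 0, dx_obesity = 0,
                    med_antihtn = 0, med_antilipemic = 0)
  for (v in vars) {
    base <- switch(v, fpg = 95, bmi = 27, sbp = 120, dbp = 75, ldl = 110,
                   hdl = 50, tg = 115)
    out[[paste0(v, "_baseline")]] <- base + seq_len(n)
    out[[paste0(v, "_ev")]] <- base + 5 + seq_len(n)
    for (k in 1:3) out[[paste0(v, "_ce_w", k)]] <- base + k + seq_len(n)
    out[[paste0(v, "_missing")]] <- 0L
  }
  out
}

# brute-force O(n^2) pair-enumeration oracle for Harrell concordance
concordance_oracle <- function(risk, time, event) {
  n <- length(risk)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]
    # identify the earlier-progressing member of a comparable pair
    if (ti < tj && event[i] == 1) { e <- i; l <- j }
    else if (tj < ti && event[j] == 1) { e <- j; l <- i }
    else if (ti == tj && event[i] + event[j] == 1) {
      e <- if (event[i] == 1) i else j; l <- if (event[i] == 1) j else i
    } else next
    comp <- comp + 1
    if (risk[e] > risk[l]) conc <- conc + 1
    else if (risk[e] == risk[l]) conc <- conc + 0.5
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# daily-resolution trapezoid oracle for windowed cumulative exposure
ce_daily_oracle <- function(dates, values, win_start, win_end,
                            baseline = as.Date("2005-01-01")) {
  x <- as.numeric(as.Date(dates)); y <- values
  agg <- tapply(y, x, mean)
  x <- as.numeric(names(agg)); y <- as.numeric(agg)
  o <- order(x); x <- x[o]; y <- y[o]
  bl <- as.numeric(baseline)
  if (max(x) < bl) { x <- c(x, bl); y <- c(y, y[length(y)]) }
  a <- as.numeric(as.Date(win_start)); b <- as.numeric(as.Date(win_end))
  if (x[1] > a) return(NA_real_)
  grid <- seq(a, b, by = 1)
  gv <- approx(x, y, xout = grid, rule = 2)$y
  sum((gv[-1] + gv[-length(gv)]) / 2) / (b - a)
}
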
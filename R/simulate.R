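# Synthetic EHR cohort generator: irregular visits, correlated risk-factor
# trajectories built from glycemic archetypes, and diabetes onset times drawn
# from a fading-memory hazard on windowed exposure history.

#' Trajectory archetypes understood by the simulator
#'
#' Labels encode the glycemic status (n = normoglycemic, p = prediabetic,
#' FPG 100-125 mg/dl) in the three pre-baseline history windows:
#' `stable_normal` (normal throughout), `pnn`, `npn`, `nnp`, `npp`, and
#' `progressive` (FPG rising steadily across the whole pre-baseline span).
#'
#' @return Character vector of archetype labels.
#' @export
archetype_names <- function() {
  c("stable_normal", "pnn", "npn", "nnp", "npp", "progressive")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults encode the
#' study conditions the pipeline is designed for: records spanning
#' 1995--2015 (history predates the analysis windows, as in a long-running
#' records registry) with baseline on 2005-01-01, three pre-baseline history
#' windows (2000--2001, 2002--2003, 2004), roughly two visits per
#' patient-year, per-variable recording probabilities that make fasting
#' glucose an intermittently measured lab, an archetype mix matching the
#' relative sizes of the episodic-prediabetes subpopulations, and a
#' piecewise-constant post-baseline hazard that loads on per-window FPG/BMI
#' exposure averages with exponentially fading weights for older windows.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; identical `(config, seed)` gives bit-identical
#'   cohorts.
#' @param start_date,baseline_date,end_date Calendar bounds of the record
#'   span, the prediction baseline, and administrative end of follow-up.
#' @param windows Four boundary dates defining the three half-open
#'   pre-baseline history windows; the last boundary must equal
#'   `baseline_date`.
#' @param visit_rate Expected visits per patient-year (homogeneous Poisson).
#' @param measure_prob Named per-variable probability that a visit records
#'   that variable (names from [traj_variables()]).
#' @param archetype_mix Named proportions over [archetype_names()]; must sum
#'   to 1.
#' @param noise_sd Named per-variable Gaussian measurement noise SD, in the
#'   variable's native units.
#' @param hazard_coefs List with numeric length-3 elements `fpg` and `bmi`:
#'   log-hazard weight per unit of (exposure - reference) in each history
#'   window, before fading.
#' @param level_jitter Named (`fpg`, `bmi`) half-widths of the uniform
#'   patient- and window-specific offset around the archetype's latent mean
#'   (native units). Gives patients their own levels and de-correlates the
#'   windows; bounded so archetype glycemic categories are preserved.
#' @param exposure_ref Named reference levels (`fpg`, `bmi`) subtracted from
#'   exposures inside the hazard; shifts only the baseline hazard scale.
#' @param baseline_hazard Events per patient-year for a patient at the
#'   reference exposures.
#' @param memory_decay Multiplicative attenuation of a window's hazard
#'   weight per 2-year window of elapsed time since that window; in `[0, 1]`,
#'   1 = no fading.
#' @param dropout_rate Rate (per year, from baseline) of the independent
#'   exponential loss-to-follow-up time; 0 disables dropout.
#' @param ineligible_frac Fraction of patients generated with records on only
#'   one side of baseline (they fail eligibility downstream); 0 disables
#'   ineligibility injection.
#' @param prevalent_dm_frac Fraction given a pre-baseline diabetes diagnosis
#'   code.
#' @param antidiabetic_frac Fraction given a pre-baseline antidiabetic
#'   medication record (suspected diabetes downstream).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [simulate_trajectory()],
#'   [simulate_event_time()]
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 100, seed = 1)
#' cfg$archetype_mix
sim_config <- function(n_patients,
                       seed,
                       start_date = "1995-01-01",
                       baseline_date = "2005-01-01",
                       end_date = "2015-12-31",
                       windows = c("2000-01-01", "2002-01-01",
                                   "2004-01-01", "2005-01-01"),
                       visit_rate = 2,
                       measure_prob = c(fpg = 0.50, bmi = 0.70, sbp = 0.80,
                                        dbp = 0.80, ldl = 0.25, hdl = 0.25,
                                        tg = 0.25),
                       archetype_mix = c(stable_normal = 0.475, pnn = 0.072,
                                         npn = 0.039, nnp = 0.035,
                                         npp = 0.029, progressive = 0.350),
                       noise_sd = c(fpg = 6, bmi = 1, sbp = 8, dbp = 5,
                                    ldl = 12, hdl = 5, tg = 25),
                       hazard_coefs = list(fpg = c(0.035, 0.035, 0.035),
                                           bmi = c(0.02, 0.02, 0.02)),
                       level_jitter = c(fpg = 4, bmi = 1.5),
                       exposure_ref = c(fpg = 92, bmi = 27),
                       baseline_hazard = 0.0045,
                       memory_decay = 0.85,
                       dropout_rate = 0.03,
                       ineligible_frac = 0.02,
                       prevalent_dm_frac = 0.02,
                       antidiabetic_frac = 0.01) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    start_date = as.Date(start_date),
    baseline_date = as.Date(baseline_date),
    end_date = as.Date(end_date),
    windows = as.Date(windows),
    visit_rate = visit_rate,
    measure_prob = measure_prob,
    archetype_mix = archetype_mix,
    noise_sd = noise_sd,
    hazard_coefs = hazard_coefs,
    level_jitter = level_jitter,
    exposure_ref = exposure_ref,
    baseline_hazard = baseline_hazard,
    memory_decay = memory_decay,
    dropout_rate = dropout_rate,
    ineligible_frac = ineligible_frac,
    prevalent_dm_frac = prevalent_dm_frac,
    antidiabetic_frac = antidiabetic_frac
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (abs(sum(cfg$archetype_mix) - 1) > 1e-8)
    stop("archetype_mix proportions must sum to 1")
  if (!all(names(cfg$archetype_mix) %in% archetype_names()))
    stop("unknown archetype in archetype_mix: ",
         paste(setdiff(names(cfg$archetype_mix), archetype_names()),
               collapse = ", "))
  if (cfg$visit_rate <= 0) stop("visit_rate must be > 0")
  if (cfg$baseline_hazard < 0) stop("baseline_hazard must be >= 0")
  if (cfg$memory_decay < 0 || cfg$memory_decay > 1)
    stop("memory_decay must lie in [0, 1]")
  if (length(cfg$windows) != 4 || is.unsorted(cfg$windows, strictly = TRUE))
    stop("windows must be four strictly increasing dates")
  if (cfg$windows[4] != cfg$baseline_date)
    stop("last window boundary must equal baseline_date")
  if (!(cfg$start_date <= cfg$windows[1]) || !(cfg$baseline_date < cfg$end_date))
    stop("require start_date <= first window and baseline_date < end_date")
  vars <- traj_variables()
  if (!all(vars %in% names(cfg$measure_prob)) ||
      !all(vars %in% names(cfg$noise_sd)))
    stop("measure_prob and noise_sd must name all of: ",
         paste(vars, collapse = ", "))
  if (length(cfg$hazard_coefs$fpg) != 3 || length(cfg$hazard_coefs$bmi) != 3)
    stop("hazard_coefs$fpg and $bmi must each have one weight per window")
  if (any(cfg$level_jitter < 0) ||
      !all(c("fpg", "bmi") %in% names(cfg$level_jitter)))
    stop("level_jitter must name nonnegative fpg and bmi half-widths")
  if (cfg$level_jitter[["fpg"]] > 4)
    stop("level_jitter['fpg'] above 4 mg/dl would break the archetype ",
         "glycemic categories")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  patients: %d (seed %d)\n", x$n_patients, x$seed))
  cat(sprintf("  records %s .. %s, baseline %s\n",
              x$start_date, x$end_date, x$baseline_date))
  cat(sprintf("  visit rate %.2f/yr, baseline hazard %.4f/yr, memory decay %.2f\n",
              x$visit_rate, x$baseline_hazard, x$memory_decay))
  cat("  archetype mix: ",
      paste(sprintf("%s %.3f", names(x$archetype_mix), x$archetype_mix),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- latent mean structure ---------------------------------------------

# per-archetype latent FPG mean in each history window and after baseline
.fpg_step_means <- rbind(
  stable_normal = c(90, 90, 90, 90),
  pnn           = c(110, 92, 92, 92),
  npn           = c(92, 110, 92, 92),
  nnp           = c(92, 92, 110, 110),
  npp           = c(92, 110, 110, 110)
)

.var_base <- c(bmi = 27, sbp = 122, dbp = 73, ldl = 111, hdl = 53, tg = 114)
.var_load <- c(bmi = 1.5, sbp = 8, dbp = 5, ldl = 10, hdl = -5, tg = 20)
.var_bump <- c(bmi = 2, sbp = 3, dbp = 2, ldl = 2, hdl = -3, tg = 15)

# progressive archetype: FPG rises linearly from 100 at the first history
# window to 110 at baseline (flat outside that span), so these patients are
# mildly prediabetic throughout the history windows
.progressive_fpg <- function(date_num, cfg) {
  w1 <- as_date_num(cfg$windows[1])
  frac <- (date_num - w1) / (as_date_num(cfg$baseline_date) - w1)
  100 + 10 * pmin(pmax(frac, 0), 1)
}

# draw the patient x window latent-level offsets (columns w1..w3, post)
draw_level_jitter <- function(n, half_width) {
  matrix(stats::runif(n * 4, -half_width, half_width), n, 4)
}

# latent FPG mean at given dates; jf is the n x 4 FPG jitter matrix and
# row indexes patients (both aligned with `archetype`)
latent_fpg <- function(archetype, date_num, cfg, jf = NULL,
                       row = seq_along(archetype)) {
  bnd <- as_date_num(cfg$windows)
  idx <- findInterval(date_num, c(bnd, Inf))      # 0 .. 4 (4 = post-baseline)
  idx[idx < 1] <- 1                               # pre-window dates: w1 mean
  idx <- pmin(idx, 4L)
  out <- numeric(length(archetype))
  prog <- archetype == "progressive"
  if (any(prog)) out[prog] <- .progressive_fpg(date_num[prog], cfg)
  if (any(!prog)) {
    rowi <- match(archetype[!prog], rownames(.fpg_step_means))
    out[!prog] <- .fpg_step_means[cbind(rowi, idx[!prog])]
  }
  if (!is.null(jf)) out <- out + jf[cbind(row, idx)]
  out
}

# per-window latent FPG averages (the exposures entering the hazard)
fpg_window_exposures <- function(archetype, cfg, jf = NULL) {
  bnd <- as_date_num(cfg$windows)
  mid <- (bnd[-4] + bnd[-1]) / 2
  out <- matrix(NA_real_, length(archetype), 3)
  prog <- archetype == "progressive"
  if (any(prog))
    out[prog, ] <- matrix(.progressive_fpg(mid, cfg), sum(prog), 3,
                          byrow = TRUE)
  if (any(!prog))
    out[!prog, ] <- .fpg_step_means[archetype[!prog], 1:3, drop = FALSE]
  if (!is.null(jf)) out <- out + jf[, 1:3, drop = FALSE]
  out
}

bmi_window_exposures <- function(archetype, z, cfg, jf = NULL, jb = NULL) {
  fpgw <- fpg_window_exposures(archetype, cfg, jf = NULL)
  out <- 27 + 1.5 * z + 2 * (fpgw >= 100)
  if (!is.null(jb)) out <- out + jb[, 1:3, drop = FALSE]
  out
}

# latent mean of any variable at given dates (vectorized over rows)
latent_mean <- function(variable, archetype, z, date_num, cfg,
                        jf = NULL, jb = NULL,
                        row = seq_along(archetype)) {
  bnd <- as_date_num(cfg$windows)
  idx <- pmin(pmax(findInterval(date_num, c(bnd, Inf)), 1L), 4L)
  fpg <- latent_fpg(archetype, date_num, cfg, jf = jf, row = row)
  fpg_nojit <- latent_fpg(archetype, date_num, cfg)
  out <- numeric(length(variable))
  is_fpg <- variable == "fpg"
  out[is_fpg] <- fpg[is_fpg]
  if (any(!is_fpg)) {
    v <- variable[!is_fpg]
    out[!is_fpg] <- .var_base[v] + .var_load[v] * z[!is_fpg] +
      .var_bump[v] * (fpg_nojit[!is_fpg] >= 100)
    bmi <- v == "bmi"
    if (!is.null(jb) && any(bmi)) {
      k <- which(!is_fpg)[bmi]
      out[k] <- out[k] + jb[cbind(row[k], idx[k])]
    }
  }
  out
}

# ---- trajectory simulation ---------------------------------------------

#' Simulate one patient's measurement trajectory
#'
#' Draws visit dates from a homogeneous Poisson process at
#' `config$visit_rate` over `[start_date, end_date]`, records each variable
#' at each visit with probability `config$measure_prob[var]`, and sets the
#' observed value to the archetype's piecewise-smooth latent mean at the
#' visit date plus Gaussian noise (truncated at physiological floors).
#'
#' Uses the current RNG state; seed externally (or via [simulate_cohort()],
#' which seeds from its config) for reproducibility.
#'
#' @param archetype One of [archetype_names()].
#' @param config A [sim_config()].
#' @param z Patient-level latent severity factor (standard normal in the
#'   cohort generator) shifting the non-glucose variables.
#' @return A `data.frame` with columns `variable`, `date` (Date), `value`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- simulate_trajectory("pnn", sim_config(1, 1))
#' head(tr)
simulate_trajectory <- function(archetype, config, z = 0) {
  validate_sim_config(config)
  if (!archetype %in% archetype_names())
    stop("unknown archetype: '", archetype, "' (expected one of ",
         paste(archetype_names(), collapse = ", "), ")")
  span <- years_between(config$start_date, config$end_date)
  nvis <- stats::rpois(1, config$visit_rate * span)
  if (nvis == 0)
    return(data.frame(variable = character(), date = as.Date(character()),
                      value = numeric()))
  dates <- as_date_num(config$start_date) +
    floor(stats::runif(nvis) * (span * .DAYS_PER_YEAR))
  vars <- traj_variables()
  grid <- expand.grid(date = dates, variable = vars,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < config$measure_prob[grid$variable]
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0)
    return(data.frame(variable = character(), date = as.Date(character()),
                      value = numeric()))
  jf <- draw_level_jitter(1, config$level_jitter[["fpg"]])
  jb <- draw_level_jitter(1, config$level_jitter[["bmi"]])
  mu <- latent_mean(grid$variable, rep(archetype, nrow(grid)),
                    rep(z, nrow(grid)), grid$date, config,
                    jf = jf, jb = jb, row = rep(1L, nrow(grid)))
  val <- mu + stats::rnorm(nrow(grid)) * config$noise_sd[grid$variable]
  val <- pmax(val, .value_floor[grid$variable])
  out <- data.frame(variable = grid$variable,
                    date = as.Date(grid$date, origin = "1970-01-01"),
                    value = as.numeric(val))
  out[order(out$variable, out$date), , drop = FALSE]
}

# ---- event-time simulation ---------------------------------------------

# decay weight of window w (gap years before baseline) at post-baseline
# year j, per 2-year window of elapsed time
.decay_weights <- function(cfg, years_post) {
  gaps <- years_between(cfg$windows[2:4], cfg$baseline_date)  # w1, w2, w3
  outer(gaps, years_post, function(g, j) cfg$memory_decay^((g + j) / 2))
}

# vectorized piecewise-exponential event-time draw; exposures are n x 3
# matrices, u a vector of uniforms; returns latent years from baseline
# (Inf = no event before `horizon` years)
piecewise_event_times <- function(fpg_w, bmi_w, cfg, u, horizon = NULL) {
  if (is.null(horizon))
    horizon <- ceiling(years_between(cfg$baseline_date, cfg$end_date))
  n <- nrow(fpg_w)
  if (any(fpg_w < 0) || any(bmi_w < 0))
    stop("exposure averages must be nonnegative")
  if (cfg$baseline_hazard == 0) return(rep(Inf, n))
  j <- 0:(horizon - 1)
  dw <- .decay_weights(cfg, j)                       # 3 x horizon
  cf <- cfg$hazard_coefs$fpg
  cb <- cfg$hazard_coefs$bmi
  ef <- sweep(fpg_w, 2, cfg$exposure_ref["fpg"])     # n x 3 centred
  eb <- sweep(bmi_w, 2, cfg$exposure_ref["bmi"])
  lp <- ef %*% (cf * dw) + eb %*% (cb * dw)          # n x horizon
  lam <- cfg$baseline_hazard * exp(lp)
  H <- t(apply(lam, 1, cumsum))
  if (n == 1) H <- matrix(H, nrow = 1)
  E <- -log(u)
  hit <- H >= E                                      # n x horizon
  first <- apply(hit, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  t_out <- rep(Inf, n)
  ok <- !is.na(first)
  if (any(ok)) {
    idx <- cbind(seq_len(n)[ok], first[ok])
    Hprev <- ifelse(first[ok] == 1, 0, H[cbind(seq_len(n)[ok],
                                               pmax(first[ok] - 1, 1))])
    t_out[ok] <- (first[ok] - 1) + (E[ok] - Hprev) / lam[idx]
  }
  t_out
}

#' Simulate one patient's diabetes onset time from exposure history
#'
#' The post-baseline hazard is piecewise-constant on yearly intervals:
#' `lambda(t) = baseline_hazard * exp(sum_w decay(w, t) * coef_w *
#' (exposure_w - ref))`, where `decay(w, t) = memory_decay^((gap_w + t) / 2)`
#' attenuates a window's weight by the time elapsed since it (in 2-year
#' window units). The event time is drawn by inverse-transform sampling of
#' the implied piecewise-exponential survival function, then censored at the
#' administrative end of follow-up and, if `dropout_rate > 0`, at an
#' independent exponential dropout time.
#'
#' @param exposure List with numeric length-3 elements `fpg` and `bmi`: the
#'   per-window exposure averages (native units, nonnegative).
#' @param config A [sim_config()].
#' @param u Optional uniform variate driving the inverse transform (for
#'   coupled comparisons); drawn from the current RNG if `NULL`.
#' @return List with `time` (years from baseline), `event` (1 = diabetes
#'   before censoring) and `latent_time` (uncensored draw, `Inf` if no event
#'   before the administrative horizon).
#' @export
simulate_event_time <- function(exposure, config, u = NULL) {
  validate_sim_config(config)
  if (!all(c("fpg", "bmi") %in% names(exposure)))
    stop("exposure must name per-window 'fpg' and 'bmi' averages")
  if (length(exposure$fpg) != 3 || length(exposure$bmi) != 3)
    stop("exposure history must cover all three pre-baseline windows")
  if (any(unlist(exposure) < 0)) stop("exposure averages must be nonnegative")
  if (is.null(u)) u <- stats::runif(1)
  horizon <- years_between(config$baseline_date, config$end_date)
  latent <- piecewise_event_times(matrix(exposure$fpg, 1),
                                  matrix(exposure$bmi, 1),
                                  config, u,
                                  horizon = ceiling(horizon))
  censor <- horizon
  if (config$dropout_rate > 0)
    censor <- min(censor, stats::rexp(1, config$dropout_rate))
  list(time = min(latent, censor),
       event = as.integer(latent <= censor),
       latent_time = latent)
}

# ---- cohort simulation -------------------------------------------------

#' Simulate a full EHR-shaped cohort
#'
#' Generates demographics, irregular measurement records, diagnosis and
#' medication records, and latent truth for `config$n_patients` patients.
#' Composes [simulate_trajectory()]-style measurement generation (vectorized)
#' with the fading-memory hazard of [simulate_event_time()]: incident
#' diabetes appears as a diabetes-category diagnosis record at the simulated
#' onset date. Hypertension/dyslipidemia diagnoses and their medication
#' classes are emitted with probabilities tied to the patient's latent
#' severity factor; small configurable fractions carry pre-baseline diabetes
#' codes, antidiabetic medication records, or one-sided record histories so
#' that downstream eligibility and exclusion rules have work to do.
#'
#' The latent truth table (archetype, per-window exposures, uncensored event
#' time) is returned for testing only and is never written by
#' [write_cohort_csv()]'s pipeline tables.
#'
#' @param config A [sim_config()].
#' @return Object of class `raw_cohort`: list with data.frames
#'   `demographics` (patient_id, birth_date, sex), `measurements`
#'   (patient_id, variable, date, value), `diagnoses` (patient_id, category,
#'   date), `medications` (patient_id, class, date), `latent`, plus the
#'   `config`.
#' @export
#' @examples
#' raw <- simulate_cohort(sim_config(n_patients = 50, seed = 7))
#' sapply(raw[c("demographics", "measurements", "diagnoses")], nrow)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  if (n <= 0) stop("n_patients must be positive")
  set.seed(config$seed)

  bl <- as_date_num(config$baseline_date)
  st <- as_date_num(config$start_date)
  en <- as_date_num(config$end_date)
  pid <- seq_len(n)

  # demographics
  age <- pmin(pmax(stats::rnorm(n, 51, 14), 18.1), 95)
  birth <- as.Date(round(bl - age * .DAYS_PER_YEAR), origin = "1970-01-01")
  sex <- ifelse(stats::runif(n) < 0.384, "M", "F")
  archetype <- sample(names(config$archetype_mix), n, replace = TRUE,
                      prob = config$archetype_mix)
  z <- stats::rnorm(n)

  # latent exposures and event times
  jf <- draw_level_jitter(n, config$level_jitter[["fpg"]])
  jb <- draw_level_jitter(n, config$level_jitter[["bmi"]])
  fpg_w <- fpg_window_exposures(archetype, config, jf = jf)
  bmi_w <- bmi_window_exposures(archetype, z, config, jf = jf, jb = jb)
  u <- stats::runif(n)
  latent_t <- piecewise_event_times(fpg_w, bmi_w, config, u)
  horizon <- years_between(config$baseline_date, config$end_date)
  dropout <- if (config$dropout_rate > 0)
    pmax(stats::rexp(n, config$dropout_rate), 0.1) else rep(Inf, n)
  fu_years <- pmin(horizon, dropout)
  event_obs <- latent_t <= fu_years

  # structural flags
  inel <- stats::runif(n) < config$ineligible_frac
  prevalent <- stats::runif(n) < config$prevalent_dm_frac
  antidiab <- stats::runif(n) < config$antidiabetic_frac

  # visit process over [start, individual follow-up end]
  fu_end <- bl + fu_years * .DAYS_PER_YEAR
  span_y <- (fu_end - st) / .DAYS_PER_YEAR
  nvis <- stats::rpois(n, config$visit_rate * span_y)
  vis_pid <- rep(pid, nvis)
  vis_date <- floor(st + stats::runif(sum(nvis)) *
                      (rep(span_y, nvis) * .DAYS_PER_YEAR))
  if (any(inel)) {
    # ineligibility injection: drop post-baseline visits
    drop_rows <- inel[vis_pid] & vis_date >= bl
    vis_pid <- vis_pid[!drop_rows]
    vis_date <- vis_date[!drop_rows]
  }

  visits <- data.table::data.table(patient_id = vis_pid, date = vis_date)

  # measurements: bernoulli-thin visits per variable, add latent mean + noise
  vars <- traj_variables()
  mlist <- lapply(vars, function(v) {
    keep <- stats::runif(nrow(visits)) < config$measure_prob[[v]]
    dt <- visits[keep]
    dt[, variable := v]
    dt
  })
  meas <- data.table::rbindlist(mlist)

  # guarantee >=1 measurement record before and after baseline for eligible
  # patients (invariant of the generator); repairs are rare at default rates
  has_pre <- pid %in% meas[date < bl, unique(patient_id)]
  has_post <- pid %in% meas[date >= bl + 1, unique(patient_id)]
  need_pre <- which(!has_pre & !inel)
  need_post <- which(!has_post & !inel)
  repair <- data.table::rbindlist(list(
    data.table::data.table(
      patient_id = need_pre,
      date = floor(st + stats::runif(length(need_pre)) * (bl - 1 - st)),
      variable = "bmi"),
    data.table::data.table(
      patient_id = need_post,
      date = floor(bl + 1 + stats::runif(length(need_post)) *
                     pmax(fu_end[need_post] - bl - 1, 1)),
      variable = "bmi")
  ))
  if (nrow(repair) > 0) meas <- rbind(meas, repair)

  mu <- latent_mean(meas$variable, archetype[meas$patient_id],
                    z[meas$patient_id], meas$date, config,
                    jf = jf, jb = jb, row = meas$patient_id)
  val <- mu + stats::rnorm(nrow(meas)) * config$noise_sd[meas$variable]
  meas[, value := pmax(val, .value_floor[variable])]
  data.table::setorder(meas, patient_id, variable, date)

  # diagnoses and medications
  rand_pre_date <- function(k) floor(st + stats::runif(k) * (bl - 1 - st))
  dx_list <- list()
  med_list <- list()

  p_htn <- stats::plogis(-1.5 + 1.1 * z)
  htn <- stats::runif(n) < p_htn
  dx_list$htn <- data.table::data.table(
    patient_id = pid[htn], category = "hypertension",
    date = rand_pre_date(sum(htn)))
  med_htn <- htn & stats::runif(n) < 0.85
  med_list$htn <- data.table::data.table(
    patient_id = pid[med_htn], class = "antihypertensive",
    date = rand_pre_date(sum(med_htn)))

  p_dys <- stats::plogis(-1.75 + 1.1 * z)
  dys <- stats::runif(n) < p_dys
  dx_list$dys <- data.table::data.table(
    patient_id = pid[dys], category = "dyslipidemia",
    date = rand_pre_date(sum(dys)))
  med_dys <- dys & stats::runif(n) < 0.85
  med_list$dys <- data.table::data.table(
    patient_id = pid[med_dys], class = "antilipemic",
    date = rand_pre_date(sum(med_dys)))

  ever_pre <- rowSums(fpg_w >= 100) > 0
  ifg <- ever_pre & stats::runif(n) < 0.3
  dx_list$ifg <- data.table::data.table(
    patient_id = pid[ifg], category = "impaired_fasting_glucose",
    date = rand_pre_date(sum(ifg)))

  obese <- (27 + 1.5 * z > 30) & stats::runif(n) < 0.5
  dx_list$ob <- data.table::data.table(
    patient_id = pid[obese], category = "obesity",
    date = rand_pre_date(sum(obese)))

  dx_list$prev <- data.table::data.table(
    patient_id = pid[prevalent], category = "diabetes",
    date = rand_pre_date(sum(prevalent)))
  med_list$antidiab <- data.table::data.table(
    patient_id = pid[antidiab], class = "antidiabetic",
    date = rand_pre_date(sum(antidiab)))

  # incident diabetes diagnosis at the simulated onset date
  inc <- which(event_obs & !inel)
  dx_list$inc <- data.table::data.table(
    patient_id = pid[inc], category = "diabetes",
    date = pmax(floor(bl + latent_t[inc] * .DAYS_PER_YEAR), bl + 1))

  dx <- data.table::rbindlist(dx_list)
  med <- data.table::rbindlist(med_list)
  data.table::setorder(dx, patient_id, date)
  data.table::setorder(med, patient_id, date)

  to_date <- function(x) as.Date(x, origin = "1970-01-01")
  out <- list(
    demographics = data.frame(patient_id = pid, birth_date = birth,
                              sex = sex, stringsAsFactors = FALSE),
    measurements = data.frame(patient_id = meas$patient_id,
                              variable = meas$variable,
                              date = to_date(meas$date),
                              value = meas$value,
                              stringsAsFactors = FALSE),
    diagnoses = data.frame(patient_id = dx$patient_id,
                           category = dx$category,
                           date = to_date(dx$date),
                           stringsAsFactors = FALSE),
    medications = data.frame(patient_id = med$patient_id,
                             class = med$class,
                             date = to_date(med$date),
                             stringsAsFactors = FALSE),
    latent = data.frame(patient_id = pid, archetype = archetype, z = z,
                        fpg_w1 = fpg_w[, 1], fpg_w2 = fpg_w[, 2],
                        fpg_w3 = fpg_w[, 3],
                        bmi_w1 = bmi_w[, 1], bmi_w2 = bmi_w[, 2],
                        bmi_w3 = bmi_w[, 3],
                        latent_event_years = latent_t,
                        followup_years = fu_years,
                        event_observed = event_obs,
                        ineligible = inel,
                        stringsAsFactors = FALSE),
    config = config
  )
  class(out) <- "raw_cohort"
  out
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat("Synthetic raw cohort:", nrow(x$demographics), "patients;",
      nrow(x$measurements), "measurements;",
      nrow(x$diagnoses), "diagnoses;",
      nrow(x$medications), "medication records\n")
  invisible(x)
}

# ---- CSV round trip ----------------------------------------------------

#' Write / read a raw cohort as long-format CSV tables
#'
#' `write_cohort_csv()` writes the four pipeline tables (`demographics.csv`,
#' `measurements.csv`, `diagnoses.csv`, `medications.csv`; ISO-8601 dates,
#' one header row, UTF-8) plus, for simulated cohorts, the latent truth as
#' `latent_truth_synthetic.csv` — a testing aid that `read_cohort_csv()`
#' deliberately never reads, so the analysis pipeline cannot leak it.
#'
#' @param raw A `raw_cohort` (or plain list with the four tables).
#' @param dir Output/input directory.
#' @return `write_cohort_csv()`: `dir`, invisibly. `read_cohort_csv()`: a
#'   `raw_cohort` with `latent = NULL`.
#' @export
write_cohort_csv <- function(raw, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("demographics", "measurements", "diagnoses", "medications")) {
    utils::write.csv(raw[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(raw$latent))
    utils::write.csv(raw$latent,
                     file.path(dir, "latent_truth_synthetic.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  rd <- function(nm, datecol) {
    df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                          stringsAsFactors = FALSE)
    df[[datecol]] <- as.Date(df[[datecol]])
    df
  }
  out <- list(
    demographics = rd("demographics", "birth_date"),
    measurements = rd("measurements", "date"),
    diagnoses = rd("diagnoses", "date"),
    medications = rd("medications", "date"),
    latent = NULL,
    config = NULL
  )
  class(out) <- "raw_cohort"
  out
}
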
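# Cox proportional-hazards model variants, backwards elimination, Breslow
# baseline hazard and risk prediction.

#' Predictor-set definitions for the four model variants
#'
#' All variants contain demographics (age, sex), the as-of-baseline
#' diagnosis and medication indicators, every variable's baseline (most
#' recent) value and the missingness indicators. On top of that:
#' `"baseline"` adds nothing, `"ce"` adds the three windowed
#' cumulative-exposure columns per variable, `"ev"` adds the five-year
#' extreme values, and `"evce"` adds both. Hence baseline < ce < evce and
#' baseline < ev < evce as column sets.
#'
#' @param variant One of `"baseline"`, `"ce"`, `"ev"`, `"evce"`.
#' @return Character vector of feature-column names.
#' @export
#' @examples
#' setdiff(variant_columns("ce"), variant_columns("baseline"))
variant_columns <- function(variant = c("baseline", "ce", "ev", "evce")) {
  variant <- match.arg(variant)
  vars <- traj_variables()
  core <- c("age", "male", "dx_htn", "dx_dyslip", "dx_ifg", "dx_obesity",
            "med_antihtn", "med_antilipemic",
            paste0(vars, "_baseline"), paste0(vars, "_missing"))
  ce <- as.vector(t(outer(vars, paste0("_ce_w", 1:3), paste0)))
  ev <- paste0(vars, "_ev")
  switch(variant,
         baseline = core,
         ce = c(core, ce),
         ev = c(core, ev),
         evce = c(core, ev, ce))
}

#' Columns never removed by backwards elimination
#'
#' Demographics and the missingness indicators encode the cohort and
#' imputation structure rather than testable clinical effects, so they stay
#' in every model.
#'
#' @return Character vector of forced-in column names.
#' @export
forced_columns <- function() {
  c("age", "male", paste0(traj_variables(), "_missing"))
}

# Breslow cumulative baseline hazard from uncentred linear predictors;
# exact identity: sum_i Lambda0(t_i) exp(lp_i) = total events
.breslow_cumhaz <- function(time, event, lp) {
  o <- order(time)
  time <- time[o]; event <- event[o]; elp <- exp(lp[o])
  # risk-set denominator at each unique event time
  ut <- unique(time[event == 1])
  rev_cum <- rev(cumsum(rev(elp)))        # sum over {i: t_i >= t} in order
  idx <- findInterval(ut, time, left.open = TRUE) + 1  # first i with t_i >= ut
  denom <- rev_cum[idx]
  d <- vapply(ut, function(t) sum(event[time == t]), numeric(1))
  data.frame(time = ut, hazard = cumsum(d / denom))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron handling of tied event
#' times) over the given feature columns and computes the Breslow estimator
#' of the cumulative baseline hazard on the uncentred covariate scale, so
#' that [predict_risk()] with an all-zero feature row returns the baseline
#' cumulative hazard itself. Constant columns, binary columns whose minor
#' class holds fewer than 5 patients (inestimable), and exactly collinear
#' columns are dropped rather than fitted (recorded in `$dropped`).
#'
#' @param features Imputed feature data.frame (see [impute_features()]).
#' @param outcomes data.frame with `time`, `event` aligned with `features`
#'   rows (e.g. the cohort table).
#' @param variables Feature columns to include (default: all of variant
#'   `"evce"` present in `features`).
#' @return Object of class `cox_fit`: `variables`, `coef`, `se`, `p`
#'   (Wald), `loglik` (at the optimum), `cumhaz` (Breslow step function),
#'   `n`, `nevent`, `dropped`.
#' @export
fit_cox <- function(features, outcomes,
                    variables = intersect(variant_columns("evce"),
                                          names(features))) {
  if (sum(outcomes$event) < 2) stop("need at least 2 events to fit")
  X <- as.matrix(features[, variables, drop = FALSE])
  if (anyNA(X)) stop("missing values in selected feature columns; ",
                     "run impute_features() first")
  # constant columns carry no information; binary columns whose minor class
  # has fewer than 5 patients are practically inestimable (near-separation)
  keep <- apply(X, 2, function(cl) {
    if (stats::sd(cl) == 0) return(FALSE)
    ucl <- unique(cl)
    if (length(ucl) == 2) min(table(cl)) >= 5 else TRUE
  })
  dropped <- variables[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) {
    # degenerate model: every covariate constant -> null fit, Breslow
    # baseline reduces to the Nelson-Aalen estimator
    df <- data.frame(.time = outcomes$time, .event = outcomes$event)
    nullfit <- survival::coxph(survival::Surv(.time, .event) ~ 1, data = df)
    out <- list(variables = character(), coef = numeric(), se = numeric(),
                p = numeric(), loglik = nullfit$loglik[1],
                cumhaz = .breslow_cumhaz(outcomes$time, outcomes$event,
                                         rep(0, nrow(features))),
                n = nrow(features), nevent = sum(outcomes$event),
                dropped = dropped)
    class(out) <- "cox_fit"
    return(out)
  }

  df <- data.frame(X, check.names = FALSE)
  df$.time <- outcomes$time
  df$.event <- outcomes$event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  # drop exactly collinear (NA coefficient) or numerically divergent
  # (|beta| > 15: separation / unstable collinear pair) columns and refit
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(iter.max = 50,
                                                      eps = 1e-10)),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  names(beta) <- gsub("`", "", names(beta))
  bad <- is.na(beta) | !is.finite(exp(beta)) | abs(beta) > 15
  if (any(bad)) {
    if (ncol(X) == 1)
      stop("complete separation suspected for: ",
           paste(names(beta)[bad], collapse = ", "))
    refit <- fit_cox(features, outcomes, colnames(X)[!bad])
    refit$dropped <- c(dropped, names(beta)[bad], refit$dropped)
    return(refit)
  }
  if (!is.null(fit$info) && isTRUE(fit$info$flag > 0))
    stop("Cox fit did not converge")
  se <- sqrt(diag(fit$var))
  names(se) <- names(beta)
  if (any(se <= 0))
    stop("degenerate fit: nonpositive standard error for ",
         paste(names(beta)[se <= 0], collapse = ", "))
  lp <- as.vector(X %*% beta)
  out <- list(
    variables = colnames(X),
    coef = beta,
    se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    loglik = fit$loglik[2],
    cumhaz = .breslow_cumhaz(outcomes$time, outcomes$event, lp),
    n = nrow(X),
    nevent = sum(outcomes$event),
    dropped = dropped
  )
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit: %d patients, %d events, %d covariates\n",
              x$n, x$nevent, length(x$coef)))
  tab <- data.frame(coef = x$coef, `exp(coef)` = exp(x$coef), se = x$se,
                    p = signif(x$p, 3), check.names = FALSE)
  print(utils::head(tab[order(tab$p), ], 12))
  if (length(x$coef) > 12) cat("  ...\n")
  invisible(x)
}

#' Hazard ratios of a Cox fit
#'
#' @param fit A [fit_cox()] object.
#' @return Named vector `exp(coef)` — the relative hazard per unit increase
#'   of each covariate.
#' @export
hazard_ratios <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  exp(fit$coef)
}

#' Backwards elimination for a Cox model
#'
#' Iteratively refits, removing the non-forced covariate with the largest
#' Wald p-value while any exceeds `alpha` (ties broken deterministically by
#' column order: the first of the tied maxima is removed).
#'
#' @inheritParams fit_cox
#' @param alpha Removal threshold on the Wald p-value.
#' @param forced Columns never removed (default [forced_columns()]).
#' @return A `cox_fit` with attribute `eliminated` listing the removed
#'   columns in removal order.
#' @export
backwards_eliminate <- function(features, outcomes,
                                variables = intersect(variant_columns("evce"),
                                                      names(features)),
                                alpha = 0.05,
                                forced = forced_columns()) {
  removed <- character()
  vars <- variables
  repeat {
    fit <- fit_cox(features, outcomes, vars)
    vars <- fit$variables   # constants/collinear may have been dropped
    cand <- setdiff(vars, forced)
    if (length(cand) == 0) break
    pv <- fit$p[cand]
    worst <- cand[which.max(pv)]
    if (pv[[which.max(pv)]] <= alpha) break
    removed <- c(removed, worst)
    vars <- setdiff(vars, worst)
    if (length(vars) == 0) break
  }
  attr(fit, "eliminated") <- removed
  fit
}

#' Uncentred linear predictor for new feature rows
#'
#' `x' beta` on the raw covariate scale — the horizon-free risk score used
#' for concordance ranking.
#'
#' @param fit A [fit_cox()] object.
#' @param features Feature rows.
#' @return Numeric vector.
#' @export
linear_predictor <- function(fit, features) {
  stopifnot(inherits(fit, "cox_fit"))
  X <- as.matrix(features[, fit$variables, drop = FALSE])
  if (anyNA(X)) stop("missing values in feature columns")
  as.vector(X %*% fit$coef)
}

#' Predicted expected event count
#'
#' Returns `Lambda0(t) * exp(x' beta)` with `t = min(horizon, followup)` —
#' the model's cumulative hazard for the patient, interpretable under the
#' counting-process view as the expected number of incident events by `t`.
#' Horizons beyond the last observed event time use the last step of the
#' Breslow curve (carried forward) and set the attribute `extrapolated`.
#'
#' @param fit A [fit_cox()] object.
#' @param features Feature rows to predict for.
#' @param horizon Prediction horizon in years (> 0).
#' @param followup Optional per-patient follow-up times; when supplied the
#'   horizon is truncated at each patient's own follow-up.
#' @return Numeric vector of expected event counts.
#' @export
predict_risk <- function(fit, features, horizon, followup = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (horizon <= 0) stop("horizon must be positive")
  t_star <- if (is.null(followup)) rep(horizon, nrow(features))
  else pmin(horizon, followup)
  ch <- fit$cumhaz
  lam <- stats::approx(c(0, ch$time), c(0, ch$hazard), xout = t_star,
                       method = "constant", f = 0, rule = 2)$y
  out <- lam * exp(linear_predictor(fit, features))
  if (any(t_star > max(ch$time)))
    attr(out, "extrapolated") <- TRUE
  out
}

# ---- JSON persistence --------------------------------------------------

#' Persist / restore a Cox fit as JSON
#'
#' Stores variable names, coefficients, standard errors and the Breslow
#' cumulative-hazard step function; numbers at full precision.
#'
#' @param fit A [fit_cox()] object.
#' @param path File path.
#' @return `write_cox_fit()`: `path` invisibly; `read_cox_fit()`: the
#'   restored `cox_fit`.
#' @export
write_cox_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cox_fit"))
  payload <- list(
    variables = fit$variables,
    coef = as.list(fit$coef),
    se = as.list(fit$se),
    loglik = fit$loglik,
    cumhaz = list(time = fit$cumhaz$time, hazard = fit$cumhaz$hazard),
    n = fit$n, nevent = fit$nevent, dropped = fit$dropped
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cox_fit
#' @export
read_cox_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- unlist(p$coef)
  se <- unlist(p$se)
  out <- list(
    variables = p$variables,
    coef = coef, se = se,
    p = 2 * stats::pnorm(-abs(coef / se)),
    loglik = p$loglik,
    cumhaz = data.frame(time = p$cumhaz$time, hazard = p$cumhaz$hazard),
    n = p$n, nevent = p$nevent,
    dropped = if (length(p$dropped)) p$dropped else character()
  )
  class(out) <- "cox_fit"
  out
}
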
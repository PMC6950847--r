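# Harrell concordance for censored data and bootstrap out-of-bag model
# comparison.

#' Harrell concordance for censored survival data
#'
#' The C-statistic over comparable patient pairs: a pair is comparable when
#' the shorter follow-up ends in an event, or when the times are equal and
#' exactly one patient has an event. A comparable pair is concordant when
#' the patient who progressed earlier carries the strictly higher risk
#' score; risk-score ties contribute 1/2.
#'
#' @param risk Numeric risk scores (higher = predicted earlier
#'   progression); any monotone transform of predicted risk gives the same
#'   value.
#' @param time Follow-up times.
#' @param event Event indicators (0/1).
#' @return Concordance in `[0, 1]`.
#' @export
#' @examples
#' harrell_concordance(c(3, 2, 1), time = c(1, 2, 3), event = c(1, 1, 1))
harrell_concordance <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  conc <- 0
  comp <- 0
  for (i in which(event == 1)) {
    later <- time > time[i]                      # i progressed first
    tied_cens <- time == time[i] & event == 0    # equal times, one event
    cmp <- later | tied_cens
    cmp[i] <- FALSE
    m <- sum(cmp)
    if (m == 0) next
    conc <- conc + sum(risk[i] > risk[cmp]) + 0.5 * sum(risk[i] == risk[cmp])
    comp <- comp + m
  }
  if (comp == 0) stop("no comparable pairs: concordance undefined")
  conc / comp
}

#' Bootstrap out-of-bag concordance evaluation
#'
#' For each of `B` bootstrap replicates: patients are resampled with
#' replacement (in-bag); each model variant is fitted on the in-bag sample
#' (with backwards elimination unless `eliminate = FALSE`); out-of-bag
#' patients are scored by the fitted linear predictor; and Harrell
#' concordance is computed on the out-of-bag sample. All variants share the
#' same replicate index sets, so the B concordance values are paired and
#' compared by paired t-tests. Imputation statistics (cohort means) are by
#' default recomputed on the in-bag sample only and applied to the
#' out-of-bag patients; `impute_before_split = TRUE` instead imputes the
#' full table once up front. Replicates whose out-of-bag sample contains no
#' events are redrawn (counted in `$redraws`).
#'
#' @param features Unimputed feature table from [build_features()] (or an
#'   imputed one with `impute_before_split = TRUE`).
#' @param outcomes data.frame with `time`, `event` aligned with `features`.
#' @param variants Character vector of model variants (see
#'   [variant_columns()]).
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; results are a pure function of the inputs and
#'   the seed.
#' @param alpha Backwards-elimination threshold.
#' @param eliminate Run backwards elimination when fitting.
#' @param reuse_selection Select variables once, by backwards elimination on
#'   the full (imputed) table, and refit only the selected columns within
#'   each replicate; default `FALSE`, the honest bootstrap that repeats
#'   selection per replicate.
#' @param impute_before_split Impute once on the full table before
#'   resampling (mirrors an analysis that imputes the whole cohort first);
#'   default `FALSE`, the leak-free order.
#' @return Object of class `concordance_result`: matrix `concordance`
#'   (B x variants), `summary` (median and quartiles per variant),
#'   `t_tests` (pairwise paired comparisons; a self-comparison has mean
#'   difference exactly 0 and `NA` p-value), `oob_frac` (per-replicate
#'   out-of-bag fraction), `redraws`.
#' @export
bootstrap_evaluate <- function(features, outcomes,
                               variants = c("baseline", "ce", "ev", "evce"),
                               B = 1000, seed = 1, alpha = 0.05,
                               eliminate = TRUE,
                               reuse_selection = FALSE,
                               impute_before_split = FALSE) {
  if (B < 2) stop("B must be at least 2")
  stopifnot(nrow(features) == nrow(outcomes))
  set.seed(seed)
  n <- nrow(features)
  if (impute_before_split) features <- impute_features(features)

  selected <- NULL
  if (reuse_selection && eliminate) {
    ft_full <- if (impute_before_split) features else impute_features(features)
    selected <- lapply(seq_along(variants), function(iv) {
      cols <- intersect(variant_columns(variants[iv]), names(features))
      backwards_eliminate(ft_full, outcomes, cols, alpha = alpha)$variables
    })
  }

  res <- matrix(NA_real_, B, length(variants),
                dimnames = list(NULL, variants))
  oob_frac <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      inbag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), inbag)
      if (length(oob) > 0 && sum(outcomes$event[oob]) > 0 &&
          sum(outcomes$event[inbag]) >= 2) break
      redraws <- redraws + 1L
    }
    oob_frac[b] <- length(oob) / n
    if (impute_before_split) {
      ft_in <- features[inbag, , drop = FALSE]
      ft_oob <- features[oob, , drop = FALSE]
    } else {
      ft_in <- impute_features(features[inbag, , drop = FALSE])
      ft_oob <- impute_features(features[oob, , drop = FALSE],
                                means = attr(ft_in, "impute_means"))
    }
    out_in <- outcomes[inbag, , drop = FALSE]
    for (iv in seq_along(variants)) {
      cols <- intersect(variant_columns(variants[iv]), names(features))
      fit <- if (!is.null(selected))
        fit_cox(ft_in, out_in, selected[[iv]])
      else if (eliminate)
        backwards_eliminate(ft_in, out_in, cols, alpha = alpha)
      else fit_cox(ft_in, out_in, cols)
      sc <- linear_predictor(fit, ft_oob)
      res[b, iv] <- harrell_concordance(sc, outcomes$time[oob],
                                        outcomes$event[oob])
    }
  }

  summ <- t(apply(res, 2, function(x)
    stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)))
  colnames(summ) <- c("q25", "median", "q75")

  pairs <- if (length(variants) >= 2)
    utils::combn(seq_along(variants), 2, simplify = FALSE)
  else list()
  tt <- lapply(pairs, function(pr) {
    d <- res[, pr[1]] - res[, pr[2]]
    p <- if (stats::sd(d) == 0) NA_real_
    else stats::t.test(res[, pr[1]], res[, pr[2]], paired = TRUE)$p.value
    data.frame(a = variants[pr[1]], b = variants[pr[2]],
               mean_diff = mean(d), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- list(concordance = res,
              summary = summ,
              t_tests = if (length(tt)) do.call(rbind, tt) else
                data.frame(a = character(), b = character(),
                           mean_diff = numeric(), p_value = numeric()),
              oob_frac = oob_frac,
              redraws = redraws,
              B = B, seed = seed)
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Bootstrap out-of-bag concordance (B = %d)\n", x$B))
  print(round(x$summary, 4))
  cat("Paired comparisons:\n")
  df <- x$t_tests
  df$mean_diff <- signif(df$mean_diff, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  if (x$redraws > 0)
    cat(sprintf("(%d replicate(s) redrawn for empty out-of-bag events)\n",
                x$redraws))
  invisible(x)
}

#' Write a concordance result to disk
#'
#' Writes the per-replicate out-of-bag concordance values as a CSV (one row
#' per replicate, one column per variant) and the summary plus paired-test
#' table as JSON.
#'
#' @param x A [bootstrap_evaluate()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_concordance_result <- function(x, dir) {
  stopifnot(inherits(x, "concordance_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(x$concordance),
                   file.path(dir, "concordance_replicates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = as.data.frame(cbind(variant = rownames(x$summary),
                                       as.data.frame(x$summary))),
         t_tests = x$t_tests,
         B = x$B, seed = x$seed, redraws = x$redraws),
    file.path(dir, "concordance_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' External comparator risk score
#'
#' Builds a fixed linear scoring function from user-supplied per-column
#' weights (for example a published paper-and-pencil diabetes risk score
#' whose coefficients are taken from its original publication). The
#' returned function maps a feature table to a risk score directly
#' comparable with model linear predictors in [harrell_concordance()]. No
#' published weights ship with this package.
#'
#' @param weights Named numeric vector: feature column -> weight.
#' @param intercept Additive constant (irrelevant for ranking).
#' @return `function(features) -> numeric` risk scores.
#' @export
#' @examples
#' score <- external_risk_score(c(age = 0.05, fpg_baseline = 0.03))
#' score(data.frame(age = c(40, 60), fpg_baseline = c(90, 110)))
external_risk_score <- function(weights, intercept = 0) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(names(weights) != ""))
  force(intercept)
  function(features) {
    miss <- setdiff(names(weights), names(features))
    if (length(miss) > 0)
      stop("features lack scoring columns: ", paste(miss, collapse = ", "))
    X <- as.matrix(features[, names(weights), drop = FALSE])
    as.vector(intercept + X %*% weights)
  }
}
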
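#' Cross-tabulate high-risk flags against observed outcomes
#'
#' @param flags,outcomes binary vectors of equal positive length.
#' @param year,threshold optional labels carried into the result.
#' @return A list of class `confusion_summary`: counts `tp`, `fp`, `tn`, `fn`,
#'   total `n`, and the four proportions (`tp_prop`, ...).
#' @export
confusion <- function(flags, outcomes, year = NA_integer_,
                      threshold = NA_integer_) {
  if (length(flags) != length(outcomes)) stop("length mismatch")
  if (length(flags) == 0L) stop("empty input")
  if (!all(flags %in% c(0, 1)) || !all(outcomes %in% c(0, 1)))
    stop("flags and outcomes must be binary 0/1")
  tp <- sum(flags == 1 & outcomes == 1)
  fp <- sum(flags == 1 & outcomes == 0)
  fn <- sum(flags == 0 & outcomes == 1)
  tn <- sum(flags == 0 & outcomes == 0)
  n <- length(flags)
  structure(list(year = year, threshold = threshold,
                 tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 tp_prop = tp / n, fp_prop = fp / n,
                 tn_prop = tn / n, fn_prop = fn / n),
            class = "confusion_summary")
}

ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' The six classification performance metrics
#'
#' Computes TPR (sensitivity), FPR (1 - specificity), PPV, NPV, F1 (harmonic
#' mean of TPR and PPV) and accuracy, plus outcome prevalence, from a
#' confusion summary. The formulas are ratios of the four cells, so counts
#' and proportions give identical results — printed proportion tables can be
#' fed straight in. A metric whose denominator is zero is returned as `NA`
#' (an explicit undefined marker), never as 0: a silent zero would fabricate
#' drift downstream.
#'
#' @param x a [confusion()] result, or any list/data.frame row with elements
#'   `tp`, `fp`, `tn`, `fn` on a common scale.
#' @return Named list of class `metric_set` with `tpr`, `fpr`, `ppv`, `npv`,
#'   `f1`, `accuracy`, `prevalence`, each a proportion in \[0,1\] or `NA`.
#' @examples
#' # published 90th-percentile classification proportions work directly
#' compute_metrics(list(tp = 0.0157, tn = 0.8843, fp = 0.0842, fn = 0.0156))
#' @export
compute_metrics <- function(x) {
  tp <- x$tp; fp <- x$fp; tn <- x$tn; fn <- x$fn
  stopifnot(is.numeric(tp), is.numeric(fp), is.numeric(tn), is.numeric(fn))
  if (min(tp, fp, tn, fn) < 0) stop("negative cell")
  n <- tp + fp + tn + fn
  if (n <= 0) stop("all cells zero")
  tpr <- ratio_or_na(tp, tp + fn)
  fpr <- ratio_or_na(fp, fp + tn)
  ppv <- ratio_or_na(tp, tp + fp)
  npv <- ratio_or_na(tn, tn + fn)
  f1 <- if (is.na(tpr) || is.na(ppv)) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  structure(list(tpr = tpr, fpr = fpr, ppv = ppv, npv = npv, f1 = f1,
                 accuracy = (tp + tn) / n, prevalence = (tp + fn) / n),
            class = "metric_set")
}

#' Calibration across ten equal-count risk deciles
#'
#' Rows are sorted by predicted probability (stable, so ties keep input
#' order) and split into `n_bins` bins whose counts differ by at most one;
#' per bin the mean prediction is compared with the observed outcome rate.
#'
#' @param probabilities predicted probabilities.
#' @param outcomes binary outcomes, same length.
#' @param n_bins number of risk bins (default 10 deciles).
#' @return data.frame: `decile`, `n`, `mean_predicted`, `observed_rate`.
#' @export
calibration_by_decile <- function(probabilities, outcomes, n_bins = 10L) {
  n <- length(probabilities)
  if (length(outcomes) != n) stop("length mismatch")
  if (n < n_bins) stop("fewer rows than bins")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary")
  ord <- order(probabilities)            # stable: ties by input order
  bin <- ceiling(seq_len(n) * n_bins / n)
  data.frame(
    decile = seq_len(n_bins),
    n = as.integer(tabulate(bin, n_bins)),
    mean_predicted = as.numeric(tapply(probabilities[ord], bin, mean)),
    observed_rate = as.numeric(tapply(outcomes[ord], bin, mean))
  )
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a randomly chosen case is scored above a randomly
#' chosen control, with ties counted one half — the Mann-Whitney formulation,
#' computed from average ranks. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param probabilities scores or probabilities.
#' @param outcomes binary outcomes, same length.
#' @return AUC in \[0,1\], or `NA` if only one class is present.
#' @export
auc <- function(probabilities, outcomes) {
  if (length(probabilities) != length(outcomes)) stop("length mismatch")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary")
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probabilities)               # average ranks: half-credit ties
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval via beta-distribution quantiles; the lower bound is exactly
#' 0 when `k = 0` and the upper exactly 1 when `k = n`.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != trunc(k) || n != trunc(n))
    stop("need integers 0 <= k <= n, n >= 1")
  a <- (1 - level) / 2
  c(lower = if (k == 0) 0 else qbeta(a, k, n - k + 1),
    upper = if (k == n) 1 else qbeta(1 - a, k + 1, n - k))
}

#' Per-year performance at a percentile threshold
#'
#' Flags each year at the threshold and assembles the confusion counts and
#' proportions, the six metrics, outcome prevalence and (optionally) AUC per
#' scoring year, with exact binomial intervals for the classification rates.
#'
#' @param scored a scored panel (`raw_probability` and `can_score` present).
#' @param threshold percentile threshold in 0-99.
#' @param exact_ci attach Clopper-Pearson intervals for the four rates and
#'   prevalence (default TRUE).
#' @param with_auc attach per-year AUC (default TRUE).
#' @return data.frame, one row per year.
#' @export
metrics_by_year <- function(scored, threshold = 90L, exact_ci = TRUE,
                            with_auc = TRUE) {
  years <- sort(unique(scored$year))
  rows <- lapply(years, function(y) {
    sel <- scored$year == y
    fl <- classify(scored[sel, , drop = FALSE], threshold)
    cs <- confusion(fl, scored$outcome[sel], year = y, threshold = threshold)
    ms <- compute_metrics(cs)
    row <- data.frame(year = y, threshold = threshold,
                      n = cs$n, tp = cs$tp, fp = cs$fp, tn = cs$tn, fn = cs$fn,
                      tp_prop = cs$tp_prop, fp_prop = cs$fp_prop,
                      tn_prop = cs$tn_prop, fn_prop = cs$fn_prop,
                      tpr = ms$tpr, fpr = ms$fpr, ppv = ms$ppv, npv = ms$npv,
                      f1 = ms$f1, accuracy = ms$accuracy,
                      prevalence = ms$prevalence)
    if (exact_ci) {
      for (cell in c("tp", "fp", "tn", "fn")) {
        ci <- binomial_ci(cs[[cell]], cs$n)
        row[[paste0(cell, "_lower")]] <- ci[["lower"]]
        row[[paste0(cell, "_upper")]] <- ci[["upper"]]
      }
      ci <- binomial_ci(cs$tp + cs$fn, cs$n)
      row$prevalence_lower <- ci[["lower"]]
      row$prevalence_upper <- ci[["upper"]]
    }
    if (with_auc)
      row$auc <- auc(scored$raw_probability[sel], scored$outcome[sel])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
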
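drift_metric_names <- c("tpr", "fpr", "ppv", "npv", "f1", "accuracy")

# row subset without data.frame row-name bookkeeping (duplicated indices
# would otherwise trigger quadratic unique-row-name generation)
subset_rows <- function(df, idx) {
  out <- lapply(df, `[`, idx)
  attr(out, "row.names") <- .set_row_names(length(idx))
  class(out) <- "data.frame"
  out
}

#' Drift evaluation periods
#'
#' A period compares a baseline scoring year with a final scoring year.
#' Labels follow the "year of risk score (year of outcome measurement)"
#' display convention, the outcome being measured the following year. The
#' default periods separate gradual pre-pandemic change (2016-2018), the
#' pandemic shock (2019-2020), and the composite span (2016-2020).
#'
#' @param baseline_year,final_year equal-length integer vectors with
#'   `baseline_year < final_year` elementwise.
#' @param label optional display labels.
#' @return data.frame with columns `baseline_year`, `final_year`, `label`.
#' @export
drift_periods <- function(baseline_year = c(2016L, 2019L, 2016L),
                          final_year = c(2018L, 2020L, 2020L),
                          label = NULL) {
  stopifnot(length(baseline_year) == length(final_year),
            all(baseline_year < final_year))
  if (is.null(label))
    label <- sprintf("%d to %d (%d-%d)", baseline_year, final_year,
                     baseline_year + 1L, final_year + 1L)
  data.frame(baseline_year = as.integer(baseline_year),
             final_year = as.integer(final_year),
             label = label, stringsAsFactors = FALSE)
}

#' Performance drift between a baseline and a final year
#'
#' Drift is the absolute change in a metric from the baseline to the final
#' year of a period, in percentage points: `(final - baseline) * 100` for
#' metrics held as proportions. The sign is final minus baseline (a PPV drop
#' is negative). A metric undefined in either year yields `NA` drift.
#'
#' @param metrics_by_year output of [metrics_by_year()] covering both years.
#' @param baseline_year,final_year scoring years present in the table.
#' @param metrics metric names to difference (default the six standard ones
#'   plus prevalence).
#' @return data.frame: `metric`, `baseline`, `final` (proportions),
#'   `change_pts` (percentage points).
#' @export
drift <- function(metrics_by_year, baseline_year, final_year,
                  metrics = c(drift_metric_names, "prevalence")) {
  b <- metrics_by_year[metrics_by_year$year == baseline_year, , drop = FALSE]
  f <- metrics_by_year[metrics_by_year$year == final_year, , drop = FALSE]
  if (nrow(b) != 1L || nrow(f) != 1L)
    stop("baseline/final year not found (or not unique) in metrics table")
  bad <- setdiff(metrics, names(metrics_by_year))
  if (length(bad)) stop("unknown metrics: ", paste(bad, collapse = ", "))
  bv <- unlist(b[metrics]); fv <- unlist(f[metrics])
  data.frame(metric = metrics,
             baseline = unname(bv), final = unname(fv),
             change_pts = unname((fv - bv) * 100),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Patients whose classification the drift implies changed
#'
#' The absolute TPR change times the final-year case count (cases no longer,
#' or newly, detected) and the absolute FPR change times the final-year
#' control count (controls newly, or no longer, falsely flagged), rounded to
#' whole persons.
#'
#' @param delta_tpr,delta_fpr metric changes as proportions (not points).
#' @param n_cases_final,n_controls_final final-year case and control counts.
#' @return Named numeric `c(cases, controls)`.
#' @export
affected_counts <- function(delta_tpr, delta_fpr, n_cases_final,
                            n_controls_final) {
  stopifnot(n_cases_final >= 0, n_controls_final >= 0)
  c(cases = round(abs(delta_tpr) * n_cases_final),
    controls = round(abs(delta_fpr) * n_controls_final))
}

#' Bootstrap configuration
#'
#' @param n_individuals patients drawn (with replacement) per replicate.
#' @param n_replicates number of bootstrap replicates.
#' @param seed RNG seed; identical seeds give identical intervals.
#' @param ci_level confidence level (default 0.95).
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_individuals = 10000L, n_replicates = 500L,
                             seed = 1L, ci_level = 0.95) {
  stopifnot(n_individuals >= 1, n_replicates >= 1,
            ci_level > 0, ci_level < 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), ci_level = ci_level),
            class = "bootstrap_config")
}

#' Individual-level bootstrap confidence intervals
#'
#' Resamples *patients* with replacement: each replicate draws
#' `n_individuals` patient ids and takes all their yearly rows (a patient
#' drawn k times contributes every row k times), which preserves
#' within-patient correlation across repeated longitudinal measures. The
#' statistic is evaluated on each resampled panel — so any percentile
#' transform inside it is recomputed per replicate — and the interval is the
#' (2.5th, 97.5th) percentile of the replicate distribution at the default
#' level. Model coefficients are never refit inside replicates. When
#' `n_individuals` is below the cohort size the intervals are conservatively
#' wide.
#'
#' @param panel a cohort panel (any data.frame with a `patient_id` column).
#' @param statistic function mapping a panel to a (possibly named) numeric
#'   vector.
#' @param config a [bootstrap_config()].
#' @param max_undefined maximum tolerated fraction of replicates in which a
#'   statistic is `NA` (default 0.1); beyond it the call fails with a
#'   diagnostic.
#' @return data.frame: `statistic`, `estimate` (full panel), `lower`,
#'   `upper`, `n_undefined`.
#' @export
bootstrap_ci <- function(panel, statistic, config = bootstrap_config(),
                         max_undefined = 0.1) {
  stopifnot(inherits(config, "bootstrap_config"))
  ids <- unique(panel$patient_id)
  rows_by_id <- split(seq_len(nrow(panel)), match(panel$patient_id, ids))
  one_row_each <- all(lengths(rows_by_id) == 1L)
  row_of_id <- if (one_row_each) unlist(rows_by_id, use.names = FALSE)
  est <- statistic(panel)
  nm <- names(est) %||% paste0("stat", seq_along(est))
  reps <- matrix(NA_real_, config$n_replicates, length(est))
  set.seed(config$seed)
  for (r in seq_len(config$n_replicates)) {
    pick <- sample.int(length(ids), config$n_individuals, replace = TRUE)
    idx <- if (one_row_each) row_of_id[pick]
           else unlist(rows_by_id[pick], use.names = FALSE)
    v <- statistic(subset_rows(panel, idx))
    if (length(v) != length(est)) stop("statistic length varies across replicates")
    reps[r, ] <- as.numeric(v)
  }
  n_na <- colSums(is.na(reps))
  bad <- n_na / config$n_replicates > max_undefined
  if (any(bad))
    stop("statistic undefined in more than ", round(100 * max_undefined),
         "% of replicates: ", paste(nm[bad], collapse = ", "),
         " (", paste(n_na[bad], collapse = ", "), " of ",
         config$n_replicates, ")")
  a <- (1 - config$ci_level) / 2
  data.frame(
    statistic = nm,
    estimate = as.numeric(est),
    lower = apply(reps, 2, quantile, probs = a, na.rm = TRUE, names = FALSE),
    upper = apply(reps, 2, quantile, probs = 1 - a, na.rm = TRUE, names = FALSE),
    n_undefined = as.integer(n_na),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# drift changes (points) for all periods x metrics from a scored panel;
# used as the bootstrap statistic, so the percentile transform is redone
# on every resampled panel while the raw probabilities stay fixed.
drift_changes_vector <- function(prob_panel, periods, threshold, metrics) {
  s <- to_percentile(prob_panel)
  my <- metrics_by_year(s, threshold, exact_ci = FALSE, with_auc = FALSE)
  out <- numeric(0)
  for (i in seq_len(nrow(periods))) {
    d <- drift(my, periods$baseline_year[i], periods$final_year[i], metrics)
    out <- c(out, setNames(d$change_pts,
                           paste(periods$label[i], d$metric, sep = "|")))
  }
  out
}

#' End-to-end drift analysis for one percentile threshold
#'
#' Scores the panel with the fixed coefficients, computes per-year metrics,
#' differences them over each period, attaches affected-patient counts for
#' TPR and FPR, and (when a bootstrap configuration is supplied)
#' individual-level bootstrap intervals for every drift estimate. Inside each
#' bootstrap replicate the raw probabilities are kept (coefficients fixed)
#' but the percentile ranking is recomputed.
#'
#' @param panel a cohort panel.
#' @param coefficients the deployed [coefficient_table()].
#' @param periods a [drift_periods()] table.
#' @param threshold percentile threshold (default 90).
#' @param metrics metric names to track.
#' @param bootstrap optional [bootstrap_config()]; `NULL` skips intervals.
#' @return data.frame with one row per period x metric: point estimates,
#'   `ci_lower`/`ci_upper` (NA without bootstrap), and `affected` counts for
#'   TPR/FPR rows.
#' @export
drift_analysis <- function(panel, coefficients, periods = drift_periods(),
                           threshold = 90L,
                           metrics = c(drift_metric_names, "prevalence"),
                           bootstrap = NULL) {
  missing_years <- setdiff(c(periods$baseline_year, periods$final_year),
                           unique(panel$year))
  if (length(missing_years))
    stop("period years absent from panel: ",
         paste(missing_years, collapse = ", "))
  prob_panel <- compute_raw_probability(panel, coefficients)
  scored <- to_percentile(prob_panel)
  my <- metrics_by_year(scored, threshold, exact_ci = FALSE, with_auc = FALSE)
  rows <- lapply(seq_len(nrow(periods)), function(i) {
    d <- drift(my, periods$baseline_year[i], periods$final_year[i], metrics)
    fy <- my[my$year == periods$final_year[i], ]
    n_cases <- fy$tp + fy$fn
    n_controls <- fy$fp + fy$tn
    d$affected <- NA_real_
    if ("tpr" %in% d$metric) {
      dt <- d$change_pts[d$metric == "tpr"] / 100
      d$affected[d$metric == "tpr"] <- affected_counts(dt, 0, n_cases, 0)[["cases"]]
    }
    if ("fpr" %in% d$metric) {
      df_ <- d$change_pts[d$metric == "fpr"] / 100
      d$affected[d$metric == "fpr"] <- affected_counts(0, df_, 0, n_controls)[["controls"]]
    }
    cbind(data.frame(period = periods$label[i],
                     baseline_year = periods$baseline_year[i],
                     final_year = periods$final_year[i],
                     threshold = threshold,
                     stringsAsFactors = FALSE), d)
  })
  out <- do.call(rbind, rows)
  out$ci_lower <- NA_real_
  out$ci_upper <- NA_real_
  if (!is.null(bootstrap)) {
    ci <- bootstrap_ci(prob_panel,
                       function(p) drift_changes_vector(p, periods, threshold, metrics),
                       config = bootstrap)
    key <- paste(out$period, out$metric, sep = "|")
    m <- match(key, ci$statistic)
    out$ci_lower <- ci$lower[m]
    out$ci_upper <- ci$upper[m]
  }
  rownames(out) <- NULL
  out
}
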
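#' Published VA CAN classification rates at the 90th percentile
#'
#' The reported national classification-rate table for the deployed CAN
#' score: per scoring year (outcome measured the following year), the total
#' participant count and the true-positive, true-negative, false-positive,
#' false-negative and outcome-prevalence percentages at the 90th percentile
#' threshold. Because the six performance metrics are ratios of the four
#' cells, these printed percentages can be fed directly to
#' [compute_metrics()] and [drift()] to recompute the reported metric values
#' and drift estimates without access to the underlying records.
#'
#' @return data.frame with columns `year`, `total_participants`, `tp_pct`,
#'   `tn_pct`, `fp_pct`, `fn_pct`, `prevalence_pct`.
#' @examples
#' rates <- published_classification_rates()
#' r20 <- rates[rates$year == 2020, ]
#' compute_metrics(list(tp = r20$tp_pct, tn = r20$tn_pct,
#'                      fp = r20$fp_pct, fn = r20$fn_pct))
#' @export
published_classification_rates <- function() {
  path <- system.file("extdata", "can_published_rates.csv",
                      package = "candrift", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Per-year metrics recomputed from a printed rate table
#'
#' Convenience wrapper turning a published rate table (percent cells) into
#' the same shape as [metrics_by_year()], so [drift()] applies unchanged.
#'
#' @param rates a table as returned by [published_classification_rates()].
#' @return data.frame with one row per year: the cell percentages and the
#'   six metrics (as proportions).
#' @export
metrics_from_published <- function(rates = published_classification_rates()) {
  rows <- lapply(seq_len(nrow(rates)), function(i) {
    ms <- compute_metrics(list(tp = rates$tp_pct[i], tn = rates$tn_pct[i],
                               fp = rates$fp_pct[i], fn = rates$fn_pct[i]))
    data.frame(year = rates$year[i],
               tp = rates$tp_pct[i], tn = rates$tn_pct[i],
               fp = rates$fp_pct[i], fn = rates$fn_pct[i],
               tpr = ms$tpr, fpr = ms$fpr, ppv = ms$ppv, npv = ms$npv,
               f1 = ms$f1, accuracy = ms$accuracy,
               prevalence = ms$prevalence)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
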
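#' Quality-metric reliability endpoints per year
#'
#' Three endpoints measure how drift degrades a palliative-care quality
#' metric built on the high-risk flag: (1) the quality metric itself — the
#' proportion of flagged patients with a palliative-care visit; (2) the
#' proportion of false positives among flagged patients (equal to 1 - PPV on
#' the same rows); and (3) the proportion of false positives among flagged
#' patients with a visit. Each gets a Clopper-Pearson interval and its
#' numerator and denominator are reported, so every proportion is
#' recomputable. Endpoint 3 is `NA` when no flagged patient had a visit.
#'
#' @param scored a scored panel with `can_score`, `outcome` and
#'   `palliative_visit` columns.
#' @param threshold percentile threshold (default 90).
#' @param level confidence level for the exact intervals.
#' @return Long data.frame: `year`, `threshold`, `endpoint`, `numerator`,
#'   `denominator`, `proportion`, `lower`, `upper`.
#' @export
quality_endpoints <- function(scored, threshold = 90L, level = 0.95) {
  if (is.null(scored$palliative_visit))
    stop("palliative_visit column missing")
  years <- sort(unique(scored$year))
  rows <- lapply(years, function(y) {
    sel <- scored$year == y
    fl <- classify(scored[sel, , drop = FALSE], threshold) == 1L
    if (!any(fl)) stop("no flagged rows in year ", y)
    visit <- scored$palliative_visit[sel] == 1L
    fp <- scored$outcome[sel] == 0L
    num <- c(quality_metric = sum(fl & visit),
             fp_share_flagged = sum(fl & fp),
             fp_share_flagged_with_visit = sum(fl & visit & fp))
    den <- c(sum(fl), sum(fl), sum(fl & visit))
    prop <- ifelse(den > 0, num / den, NA_real_)
    ci <- t(vapply(seq_along(num), function(i) {
      if (den[i] > 0) binomial_ci(num[[i]], den[i], level)
      else c(lower = NA_real_, upper = NA_real_)
    }, numeric(2)))
    data.frame(year = y, threshold = threshold, endpoint = names(num),
               numerator = as.integer(num), denominator = as.integer(den),
               proportion = unname(prop),
               lower = ci[, 1], upper = ci[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quality-impact endpoints across years and thresholds
#'
#' Stacks [quality_endpoints()] over several percentile thresholds — by
#' default the operational 90th plus the 98th and 99th — into one tidy table
#' of endpoint x year x threshold rows.
#'
#' @param scored a scored panel.
#' @param thresholds percentile thresholds (default `c(90, 98, 99)`).
#' @param level confidence level.
#' @return Long data.frame as in [quality_endpoints()].
#' @export
impact_trend <- function(scored, thresholds = c(90L, 98L, 99L),
                         level = 0.95) {
  if (length(unique(scored$year)) < 2L)
    stop("need at least two years for a trend")
  out <- do.call(rbind, lapply(thresholds, function(t)
    quality_endpoints(scored, t, level)))
  rownames(out) <- NULL
  out
}
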
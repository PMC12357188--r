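#' Apply a fixed logistic model to a cohort panel
#'
#' Computes the raw 90-day outcome probability per patient-year as
#' `plogis(intercept + sum(coefficient * indicator))` using the frozen
#' coefficients of the deployed algorithm; nothing is refit.
#'
#' @param panel a cohort panel (see [read_panel()] for the schema).
#' @param coefficients a [coefficient_table()]; every coefficient covariate
#'   must be a 0/1 column of `panel`.
#' @return `panel` with a `raw_probability` column appended.
#' @export
compute_raw_probability <- function(panel, coefficients) {
  beta <- ct_beta(coefficients)
  missing <- setdiff(names(beta), names(panel))
  if (length(missing))
    stop("covariates missing from panel: ", paste(missing, collapse = ", "))
  X <- as.matrix(panel[names(beta)])
  if (!is.numeric(X) || !all(X %in% c(0, 1)))
    stop("covariate columns must be binary 0/1")
  panel$raw_probability <- plogis(ct_intercept(coefficients) + drop(X %*% beta))
  panel
}

#' Transform raw probabilities to 0-99 percentile scores within year
#'
#' Within each scoring year, the score of a row is
#' `floor(100 * (# rows with strictly smaller raw probability) / n)`, an
#' integer in 0-99; tied probabilities share a score. Ranking never pools
#' years, so changes in yearly cohort size cannot leak across years.
#'
#' @param scored a panel with a `raw_probability` column.
#' @return `scored` with an integer `can_score` column appended.
#' @export
to_percentile <- function(scored) {
  if (is.null(scored$raw_probability))
    stop("raw_probability column missing; run compute_raw_probability() first")
  if (nrow(scored) == 0L) stop("empty panel")
  scored$can_score <- as.integer(ave(
    scored$raw_probability, scored$year,
    FUN = function(x) floor(100 * (rank(x, ties.method = "min") - 1) / length(x))
  ))
  scored
}

#' @rdname compute_raw_probability
#' @details `score_panel()` composes [compute_raw_probability()] and
#'   [to_percentile()].
#' @export
score_panel <- function(panel, coefficients) {
  to_percentile(compute_raw_probability(panel, coefficients))
}

#' Flag high-risk rows at a percentile threshold
#'
#' @param scored a panel with a `can_score` column.
#' @param threshold_percentile integer in 0-99; rows with
#'   `can_score >= threshold_percentile` are flagged (inclusive, as in
#'   "CAN >= 90").
#' @return Integer 0/1 vector, one element per row.
#' @export
classify <- function(scored, threshold_percentile) {
  if (is.null(scored$can_score))
    stop("can_score column missing; run to_percentile() first")
  t <- threshold_percentile
  if (length(t) != 1L || is.na(t) || t != trunc(t) || t < 0 || t > 99)
    stop("threshold_percentile must be a single integer in [0, 99]")
  as.integer(scored$can_score >= t)
}
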
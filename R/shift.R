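#' Standardized mean difference of two Bernoulli prevalences
#'
#' The pooled-variance form standard in covariate balance diagnostics:
#' `(p_b - p_a) / sqrt((p_a(1-p_a) + p_b(1-p_b)) / 2)`. Defined as 0 when
#' both prevalences are 0 or both are 1 (no variance, no difference). The
#' sign convention is later minus earlier, matching drift's final-minus-
#' baseline.
#'
#' @param p_a,p_b prevalences in \[0,1\] (vectorized).
#' @return SMD values.
#' @export
smd_from_prevalence <- function(p_a, p_b) {
  stopifnot(all(p_a >= 0 & p_a <= 1), all(p_b >= 0 & p_b <= 1))
  v <- (p_a * (1 - p_a) + p_b * (1 - p_b)) / 2
  out <- ifelse(v > 0, (p_b - p_a) / sqrt(v), NA_real_)
  out[v == 0 & p_a == p_b] <- 0
  if (anyNA(out)) stop("degenerate prevalences with unequal values")
  out
}

#' Covariate shift between two years of a panel
#'
#' @param panel a cohort panel.
#' @param covariate a binary covariate column name.
#' @param year_a,year_b earlier and later scoring years.
#' @return The SMD of the covariate's prevalence, `year_b` minus `year_a`.
#' @export
smd <- function(panel, covariate, year_a, year_b) {
  if (!covariate %in% names(panel))
    stop("covariate absent from panel: ", covariate)
  a <- panel[[covariate]][panel$year == year_a]
  b <- panel[[covariate]][panel$year == year_b]
  if (length(a) == 0L || length(b) == 0L) stop("year absent from panel")
  if (!all(c(a, b) %in% c(0, 1))) stop("covariate must be binary")
  smd_from_prevalence(mean(a), mean(b))
}

#' Per-covariate shift records for a period
#'
#' Computes, for every covariate in the coefficient table, the prevalence in
#' each year, the SMD between them, and the original-model odds ratio — the
#' quadrant data behind an SMD-versus-OR shift plot.
#'
#' @param panel a cohort panel.
#' @param coefficients the deployed [coefficient_table()].
#' @param year_a,year_b earlier and later scoring years.
#' @return data.frame: `covariate`, `category`, `prevalence_a`,
#'   `prevalence_b`, `smd`, `original_or`.
#' @seealso [screen_shifts()]
#' @export
shift_table <- function(panel, coefficients, year_a, year_b) {
  beta <- ct_beta(coefficients)
  covs <- names(beta)
  missing <- setdiff(covs, names(panel))
  if (length(missing))
    stop("covariates absent from panel: ", paste(missing, collapse = ", "))
  sel_a <- panel$year == year_a
  sel_b <- panel$year == year_b
  if (!any(sel_a) || !any(sel_b)) stop("year absent from panel")
  p_a <- colMeans(panel[sel_a, covs, drop = FALSE])
  p_b <- colMeans(panel[sel_b, covs, drop = FALSE])
  keep <- coefficients$covariate != "(Intercept)"
  data.frame(covariate = covs,
             category = coefficients$category[keep][match(covs, coefficients$covariate[keep])],
             prevalence_a = unname(p_a), prevalence_b = unname(p_b),
             smd = smd_from_prevalence(unname(p_a), unname(p_b)),
             original_or = unname(exp(beta)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen shift records against SMD and odds-ratio thresholds
#'
#' A covariate is flagged as potentially associated with drift when its
#' distribution shifted strongly (`smd >= smd_cut` or `smd < -smd_cut`)
#' and/or its original predictive effect is large (`OR >= or_high` or
#' `OR < or_low`). The screen is a pure threshold function of the records:
#' permutation-invariant and idempotent.
#'
#' @param records a [shift_table()] result (columns `smd`, `original_or`).
#' @param smd_cut SMD magnitude threshold (default 0.1).
#' @param or_low,or_high odds-ratio thresholds (defaults 0.5 and 1.5).
#' @return `records` with logical columns `flagged_by_smd`, `flagged_by_or`,
#'   `flagged` (either) appended, sorted by `|smd|` descending; the flagged
#'   subset is `records[records$flagged, ]`.
#' @export
screen_shifts <- function(records, smd_cut = 0.1, or_low = 0.5,
                          or_high = 1.5) {
  stopifnot(all(c("smd", "original_or") %in% names(records)))
  records$flagged_by_smd <- records$smd >= smd_cut | records$smd < -smd_cut
  records$flagged_by_or <- records$original_or >= or_high |
    records$original_or < or_low
  records$flagged <- records$flagged_by_smd | records$flagged_by_or
  records <- records[order(-abs(records$smd)), , drop = FALSE]
  rownames(records) <- NULL
  records
}

# expand an exclusion set to whole mutually exclusive dummy groups
expand_exclusions <- function(exclude, groups) {
  if (is.null(groups)) return(exclude)
  g <- groups[exclude]
  g <- g[!is.na(g)]
  union(exclude, names(groups)[groups %in% g])
}

#' Retrain the logistic model on one year, optionally excluding covariates
#'
#' Maximum-likelihood logistic fit of the outcome on the remaining
#' covariates of a single training year (relative deviance convergence
#' 1e-8, at most 100 iterations). When a coefficient table with `group`
#' labels is supplied, excluding any dummy level of a categorical drops its
#' sibling levels too (dropping one dummy alone would silently redefine the
#' variable's reference level); disable with `expand_groups = FALSE`. Rank
#' deficiency fails naming the collinear columns; non-convergence and
#' apparent separation fail with a diagnostic.
#'
#' @param panel a cohort panel.
#' @param train_year scoring year to fit on.
#' @param exclude covariate names to drop before fitting.
#' @param coefficients optional original [coefficient_table()], used for
#'   category/group labels of the refit covariates.
#' @param expand_groups drop sibling dummy levels of excluded covariates
#'   (default TRUE).
#' @return A [coefficient_table()] of fitted log-odds coefficients.
#' @export
retrain <- function(panel, train_year, exclude = character(),
                    coefficients = NULL, expand_groups = TRUE) {
  dat <- panel[panel$year == train_year, , drop = FALSE]
  if (nrow(dat) == 0L) stop("train_year absent from panel")
  covs <- panel_covariates(panel)
  bad <- setdiff(exclude, covs)
  if (length(bad))
    stop("exclusions are not panel covariates: ", paste(bad, collapse = ", "))
  groups <- NULL
  if (!is.null(coefficients) && !is.null(coefficients$group)) {
    keep <- coefficients$covariate != "(Intercept)"
    groups <- setNames(coefficients$group[keep], coefficients$covariate[keep])
  }
  if (expand_groups) exclude <- expand_exclusions(exclude, groups)
  covs <- setdiff(covs, exclude)
  X <- cbind(`(Intercept)` = 1, as.matrix(dat[covs]))
  if (length(covs)) {
    q <- qr(X)
    if (q$rank < ncol(X)) {
      dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
      stop("rank-deficient design; collinear columns: ",
           paste(dropped, collapse = ", "))
    }
  }
  fit <- glm.fit(X, dat$outcome, family = binomial(),
                 control = glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("logistic refit did not converge")
  cf <- coef(fit)
  if (any(abs(cf) > 15))
    stop("implausibly large coefficients; possible separation: ",
         paste(names(cf)[abs(cf) > 15], collapse = ", "))
  cats <- rep(NA_character_, length(covs))
  grps <- rep(NA_character_, length(covs))
  if (!is.null(coefficients)) {
    m <- match(covs, coefficients$covariate)
    cats <- coefficients$category[m]
    grps <- coefficients$group[m]
  }
  coefficient_table(cf[["(Intercept)"]], cf[covs],
                    categories = cats, groups = grps)
}

#' Compare drift across retraining variants (ablation)
#'
#' Reruns the identical score-rank-metric-drift pipeline under alternative
#' coefficient sets: the original deployed coefficients; a baseline-year
#' refit excluding the shift-flagged covariates (the ablation proper,
#' optionally also one refit per covariate category); and full-covariate
#' refits on later years. Side-by-side drift tables show whether removing
#' the flagged inputs, or simply retraining later, alleviates drift.
#'
#' @param panel a cohort panel.
#' @param coefficients the deployed [coefficient_table()].
#' @param flagged covariate names to exclude in the ablation variant; when
#'   `NULL` they are determined by [screen_shifts()] on the composite (first
#'   baseline to last final year) period.
#' @param periods a [drift_periods()] table.
#' @param threshold percentile threshold.
#' @param train_year year the ablation refit is trained on (default the
#'   earliest baseline year).
#' @param retrain_years years for full-covariate refit variants (default
#'   2018 and 2019 when present in the periods' span, else none).
#' @param per_category also refit excluding the flagged covariates of each
#'   category separately (default FALSE).
#' @param bootstrap optional [bootstrap_config()] forwarded to
#'   [drift_analysis()].
#' @return Long data.frame of [drift_analysis()] rows with a `variant`
#'   column.
#' @export
ablation_compare <- function(panel, coefficients, flagged = NULL,
                             periods = drift_periods(), threshold = 90L,
                             train_year = min(periods$baseline_year),
                             retrain_years = NULL, per_category = FALSE,
                             bootstrap = NULL) {
  if (is.null(flagged)) {
    st <- shift_table(panel, coefficients, min(periods$baseline_year),
                      max(periods$final_year))
    st <- screen_shifts(st)
    flagged <- st$covariate[st$flagged]
  }
  if (is.null(retrain_years))
    retrain_years <- intersect(c(2018L, 2019L), unique(panel$year))
  variants <- list(original = coefficients)
  variants[["retrain_excluding_flagged"]] <-
    retrain(panel, train_year, exclude = flagged, coefficients = coefficients)
  for (y in retrain_years)
    variants[[paste0("retrain_full_", y)]] <-
      retrain(panel, y, coefficients = coefficients)
  if (per_category) {
    keep <- coefficients$covariate != "(Intercept)"
    cat_of <- setNames(coefficients$category[keep], coefficients$covariate[keep])
    for (cc in unique(cat_of[flagged])) {
      sub <- flagged[cat_of[flagged] %in% cc]
      variants[[paste0("retrain_excluding_", cc)]] <-
        retrain(panel, train_year, exclude = sub, coefficients = coefficients)
    }
  }
  out <- lapply(names(variants), function(v) {
    d <- drift_analysis(panel, variants[[v]], periods = periods,
                        threshold = threshold, bootstrap = bootstrap)
    cbind(data.frame(variant = v, stringsAsFactors = FALSE), d)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
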
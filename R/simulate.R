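#' Configure a synthetic longitudinal cohort
#'
#' Defines the generating model for a patient-year panel: independent (or
#' grouped mutually exclusive) Bernoulli covariate indicators with per-year
#' prevalences, a logistic outcome model with fixed covariate coefficients, a
#' patient-level frailty term on the logit scale that induces within-patient
#' correlation across years, optional per-year outcome prevalence targets met
#' by intercept calibration, and a palliative-care visit flag whose
#' probability increases with the raw risk.
#'
#' @param n_patients number of patients; every patient contributes one row per
#'   year.
#' @param years strictly increasing integer scoring years.
#' @param covariates data.frame with columns `name`, `category` (one of the
#'   five CAN categories), `prevalence` in (0,1), and optionally `group`: rows
#'   sharing a non-`NA` group are mutually exclusive dummy levels of one
#'   categorical variable (their prevalences must sum to < 1; the remainder is
#'   the reference level).
#' @param coefficients named numeric vector of true log-odds coefficients, one
#'   per covariate row.
#' @param intercept baseline log-odds intercept (before any per-year
#'   calibration).
#' @param shifts optional data.frame `(covariate, year, prevalence)`: from
#'   `year` onward (until overridden by a later entry) the covariate is drawn
#'   with the new prevalence. This scripts covariate shift.
#' @param prevalence_targets optional per-year outcome prevalences in (0,1)
#'   (length 1 or `length(years)`); when given, the intercept is calibrated
#'   per year by root-finding on the mean predicted probability of the
#'   realized covariate and frailty draws, so realized prevalence matches the
#'   target in expectation.
#' @param frailty_sd standard deviation of the patient-level normal frailty
#'   added to the logit; 0 gives independent years.
#' @param palliative length-2 numeric `c(intercept, slope)` of the visit
#'   model `P(visit) = plogis(intercept + slope * logit(p))`, `p` the row's
#'   true outcome probability.
#' @param seed integer RNG seed; identical configurations generate
#'   bit-identical panels.
#' @return A list of class `sim_config`.
#' @seealso [generate_cohort()], [default_scenario()]
#' @export
sim_config <- function(n_patients, years, covariates, coefficients,
                       intercept = -4, shifts = NULL,
                       prevalence_targets = NULL, frailty_sd = 0,
                       palliative = c(intercept = -1.8, slope = 1),
                       seed = 1L) {
  stopifnot(length(n_patients) == 1L, n_patients >= 1,
            n_patients == as.integer(n_patients))
  years <- as.integer(years)
  if (length(years) < 1L || anyNA(years) || any(diff(years) <= 0))
    stop("years must be strictly increasing integers")
  stopifnot(is.data.frame(covariates),
            all(c("name", "category", "prevalence") %in% names(covariates)))
  if (anyDuplicated(covariates$name))
    stop("covariate names must be unique")
  if (!all(covariates$category %in% can_categories))
    stop("covariate categories must be among: ",
         paste(can_categories, collapse = ", "))
  if (!all(covariates$prevalence > 0 & covariates$prevalence < 1))
    stop("covariate prevalences must be in (0,1)")
  if (is.null(covariates$group)) covariates$group <- NA_character_
  for (g in unique(covariates$group[!is.na(covariates$group)])) {
    if (sum(covariates$prevalence[covariates$group %in% g]) >= 1)
      stop("prevalences of group '", g, "' must sum to < 1")
  }
  if (!setequal(names(coefficients), covariates$name))
    stop("coefficients must be named exactly by the covariates")
  coefficients <- coefficients[covariates$name]
  if (!is.null(shifts)) {
    stopifnot(is.data.frame(shifts),
              all(c("covariate", "year", "prevalence") %in% names(shifts)))
    if (!all(shifts$covariate %in% covariates$name))
      stop("shift covariates not in covariate spec: ",
           paste(setdiff(shifts$covariate, covariates$name), collapse = ", "))
    if (!all(shifts$year %in% years))
      stop("shift years must be scoring years")
    if (!all(shifts$prevalence > 0 & shifts$prevalence < 1))
      stop("shift prevalences must be in (0,1)")
  }
  if (!is.null(prevalence_targets)) {
    prevalence_targets <- rep_len(prevalence_targets, length(years))
    if (!all(prevalence_targets > 0 & prevalence_targets < 1))
      stop("prevalence targets must be in (0,1)")
    names(prevalence_targets) <- years
  }
  stopifnot(length(frailty_sd) == 1L, frailty_sd >= 0)
  palliative <- unname(as.numeric(palliative))
  stopifnot(length(palliative) == 2L, all(is.finite(palliative)))
  structure(list(
    n_patients = as.integer(n_patients), years = years,
    covariates = covariates, coefficients = coefficients,
    intercept = intercept, shifts = shifts,
    prevalence_targets = prevalence_targets, frailty_sd = frailty_sd,
    palliative = palliative, seed = as.integer(seed)
  ), class = "sim_config")
}

# per-year prevalence matrix (covariate x year), shifts persisting onward
prevalence_schedule <- function(config) {
  sched <- matrix(config$covariates$prevalence,
                  nrow = nrow(config$covariates), ncol = length(config$years),
                  dimnames = list(config$covariates$name, config$years))
  sh <- config$shifts
  if (!is.null(sh)) {
    sh <- sh[order(sh$year), , drop = FALSE]
    for (i in seq_len(nrow(sh))) {
      from <- which(config$years >= sh$year[i])
      sched[sh$covariate[i], from] <- sh$prevalence[i]
    }
  }
  sched
}

# one year's covariate matrix; grouped dummies are mutually exclusive
draw_covariates <- function(n, covariates, prev) {
  k <- nrow(covariates)
  X <- matrix(0L, n, k, dimnames = list(NULL, covariates$name))
  done <- rep(FALSE, k)
  for (j in seq_len(k)) {
    if (done[j]) next
    g <- covariates$group[j]
    if (is.na(g)) {
      X[, j] <- rbinom(n, 1L, prev[j])
      done[j] <- TRUE
    } else {
      idx <- which(covariates$group %in% g)
      cum <- cumsum(prev[idx])
      lev <- findInterval(runif(n), cum) + 1L  # > length(idx) = reference
      for (m in seq_along(idx)) X[, idx[m]] <- as.integer(lev == m)
      done[idx] <- TRUE
    }
  }
  X
}

calibrate_intercept <- function(eta_no_int, intercept, target) {
  f <- function(d) mean(plogis(eta_no_int + intercept + d)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("unreachable prevalence target ", target,
         ": intercept adjustment does not bracket a solution")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a longitudinal synthetic cohort with known ground truth
#'
#' Draws one row per patient per year under a [sim_config()]: covariate
#' indicators with that year's prevalence, outcomes from the logistic model on
#' covariates plus a patient-level frailty drawn once and reused every year,
#' and a palliative-visit flag increasing in the true risk. When the
#' configuration carries outcome prevalence targets, the intercept is
#' calibrated per year by deterministic root-finding on the mean predicted
#' probability.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (data.frame: `patient_id`, `year`, one
#'   0/1 column per covariate, `outcome`, `palliative_visit`) and
#'   `coefficients` (the ground-truth [coefficient_table()] actually used; its
#'   intercept is the first year's calibrated value, and per-year intercepts
#'   are kept in the attribute `year_intercepts`).
#' @examples
#' cov <- data.frame(name = c("chf", "admit0"),
#'                   category = c("diagnostic", "utilization"),
#'                   prevalence = c(0.05, 0.85))
#' cfg <- sim_config(500, 2016:2017, cov,
#'                   c(chf = log(2), admit0 = log(0.4)), intercept = -3)
#' cohort <- generate_cohort(cfg)
#' head(cohort$panel)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  beta <- config$coefficients
  sched <- prevalence_schedule(config)
  frailty <- if (config$frailty_sd > 0) rnorm(n, 0, config$frailty_sd) else rep(0, n)
  year_int <- setNames(numeric(length(config$years)), config$years)
  out <- vector("list", length(config$years))
  pid <- sprintf("P%07d", seq_len(n))
  for (yi in seq_along(config$years)) {
    y <- config$years[yi]
    X <- draw_covariates(n, config$covariates, sched[, yi])
    eta0 <- drop(X %*% beta) + frailty
    delta <- if (!is.null(config$prevalence_targets))
      calibrate_intercept(eta0, config$intercept, config$prevalence_targets[[yi]])
    else 0
    year_int[yi] <- config$intercept + delta
    p <- plogis(eta0 + year_int[yi])
    outcome <- rbinom(n, 1L, p)
    pv <- rbinom(n, 1L, plogis(config$palliative[1] + config$palliative[2] * qlogis(p)))
    out[[yi]] <- data.frame(patient_id = pid, year = y, X, outcome = outcome,
                            palliative_visit = pv, stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  ct <- coefficient_table(year_int[1], beta,
                          categories = config$covariates$category,
                          groups = config$covariates$group)
  attr(ct, "year_intercepts") <- year_int
  list(panel = panel, coefficients = ct)
}

#' Default drift scenario
#'
#' A documented fixture emulating the qualitative drift story of a nationally
#' deployed risk score across five scoring years: 25 binary covariates over
#' the five CAN categories (the three age dummies form a mutually exclusive
#' group), outcome prevalence declining monotonically from 3.8% to 3.0%,
#' diagnostic and pharmacy covariates stable, and pandemic-style shifts from
#' the fourth year onward in one demographic (care priority status), three
#' laboratory/vital and four utilization indicators, each with analytic
#' |SMD| >= 0.2.
#'
#' @param n_patients cohort size per year (default 100000).
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
default_scenario <- function(n_patients = 100000, seed = 1L) {
  covs <- data.frame(
    name = c("female", "age_lt_55", "age_55_64", "age_65_74",
             "priority_level_0", "race_black",
             "dementia", "chf", "metastatic_cancer", "copd", "diabetes",
             "albumin_gt_3p4", "bun_0_16", "pulse_lt_60", "resp_lt_18",
             "bp_lt_110",
             "opioid_rx", "anticoagulant_rx", "insulin_rx",
             "polypharmacy_10plus",
             "admissions_0", "office_visits_0", "telehealth_use",
             "bed_days_level_0", "er_visits_2plus"),
    category = c(rep("demographic", 6), rep("diagnostic", 5),
                 rep("laboratory_vitals", 5), rep("pharmacy", 4),
                 rep("utilization", 5)),
    prevalence = c(0.09, 0.25, 0.25, 0.25, 0.30, 0.18,
                   0.042, 0.048, 0.08, 0.12, 0.25,
                   0.55, 0.45, 0.12, 0.50, 0.18,
                   0.15, 0.08, 0.10, 0.20,
                   0.85, 0.25, 0.10, 0.80, 0.12),
    group = c(NA, "age", "age", "age", NA, NA, rep(NA, 19)),
    stringsAsFactors = FALSE
  )
  or <- c(female = 0.9, age_lt_55 = 0.4, age_55_64 = 0.6, age_65_74 = 0.8,
          priority_level_0 = 0.7, race_black = 1.0,
          dementia = 2.2, chf = 1.8, metastatic_cancer = 2.5, copd = 1.4,
          diabetes = 1.2,
          albumin_gt_3p4 = 0.5, bun_0_16 = 0.6, pulse_lt_60 = 0.9,
          resp_lt_18 = 0.8, bp_lt_110 = 1.1,
          opioid_rx = 1.3, anticoagulant_rx = 1.5, insulin_rx = 1.4,
          polypharmacy_10plus = 1.6,
          admissions_0 = 0.3, office_visits_0 = 0.8, telehealth_use = 1.1,
          bed_days_level_0 = 0.4, er_visits_2plus = 1.7)
  shifts <- data.frame(
    covariate = c("priority_level_0", "albumin_gt_3p4", "bun_0_16",
                  "resp_lt_18", "admissions_0", "office_visits_0",
                  "telehealth_use", "bed_days_level_0"),
    year = 2019L,
    prevalence = c(0.42, 0.40, 0.35, 0.38, 0.92, 0.45, 0.35, 0.88),
    stringsAsFactors = FALSE
  )
  sim_config(n_patients = n_patients, years = 2016:2020,
             covariates = covs, coefficients = log(or), intercept = -4,
             shifts = shifts,
             prevalence_targets = c(0.038, 0.036, 0.034, 0.032, 0.030),
             frailty_sd = 0.8, seed = seed)
}
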
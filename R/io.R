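#' Read and validate a cohort panel CSV
#'
#' The panel schema is one row per patient-year: `patient_id`, `year`,
#' `outcome` (0/1), optionally `palliative_visit` (0/1), and every remaining
#' column a 0/1 covariate indicator. Duplicate `(patient_id, year)` pairs and
#' non-binary values are rejected with the offending rows named.
#'
#' @param path CSV file path.
#' @return Validated panel data.frame.
#' @export
read_panel <- function(path) {
  panel <- read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
}

#' @rdname read_panel
#' @details `validate_panel()` applies the same checks to an in-memory
#'   data.frame and returns it invisibly unchanged.
#' @export
validate_panel <- function(panel) {
  required <- c("patient_id", "year", "outcome")
  missing <- setdiff(required, names(panel))
  if (length(missing))
    stop("panel is missing required columns: ", paste(missing, collapse = ", "))
  key <- paste(panel$patient_id, panel$year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (patient_id, year) rows, e.g. (",
         panel$patient_id[dup[1]], ", ", panel$year[dup[1]],
         ") at row ", dup[1])
  binary_cols <- c("outcome",
                   intersect("palliative_visit", names(panel)),
                   panel_covariates(panel))
  for (cl in binary_cols) {
    bad <- which(!(panel[[cl]] %in% c(0, 1)))
    if (length(bad))
      stop("non-binary values in column '", cl, "' at rows: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  panel
}

#' @rdname read_panel
#' @param panel a panel data.frame.
#' @export
write_panel <- function(panel, path) {
  write.csv(validate_panel(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a coefficient table CSV
#'
#' Columns `covariate`, `category`, `coefficient` and optionally `group`;
#' the intercept is the `"(Intercept)"` row.
#'
#' @param path CSV file path.
#' @return A [coefficient_table()].
#' @export
read_coefficients <- function(path) {
  as_coefficient_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_coefficients
#' @param coefficients a [coefficient_table()].
#' @export
write_coefficients <- function(coefficients, path) {
  write.csv(as.data.frame(coefficients), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# small rolling fingerprint (djb2 mod 2^31-1) of the serialized config;
# identifies a run configuration in output headers
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE, null = "null")
  bytes <- as.integer(charToRaw(s))
  h <- 5381
  m <- 2147483647
  for (b in bytes) h <- (h * 33 + b) %% m
  sprintf("%08x", h)
}

#' Assemble a pipeline run configuration
#'
#' @param panel a panel data.frame, or `panel_path` to a CSV.
#' @param coefficients a [coefficient_table()], or `coefficients_path`.
#' @param panel_path,coefficients_path file alternatives to in-memory
#'   objects.
#' @param out_dir optional output directory; when given, [run_all()] writes
#'   the report tables and a machine-readable JSON there.
#' @param periods a [drift_periods()] table.
#' @param thresholds percentile thresholds for the year-by-threshold metric
#'   tables (default the operational 90 plus sensitivity thresholds).
#' @param primary_threshold threshold for drift, shift and ablation.
#' @param impact_thresholds thresholds for the quality-impact table.
#' @param bootstrap a [bootstrap_config()], or `NULL` for point estimates
#'   only.
#' @param smd_cut,or_low,or_high screening thresholds (see
#'   [screen_shifts()]).
#' @param ablation run the ablation retraining comparison (default TRUE).
#' @param seed seed recorded and used for the bootstrap when `bootstrap` is
#'   `NULL`-seeded.
#' @return list of class `run_config`.
#' @export
run_config <- function(panel = NULL, coefficients = NULL,
                       panel_path = NULL, coefficients_path = NULL,
                       out_dir = NULL, periods = drift_periods(),
                       thresholds = c(50L, 70L, 90L, 95L, 98L, 99L),
                       primary_threshold = 90L,
                       impact_thresholds = c(90L, 98L, 99L),
                       bootstrap = bootstrap_config(),
                       smd_cut = 0.1, or_low = 0.5, or_high = 1.5,
                       ablation = TRUE, seed = 1L) {
  if (is.null(panel) && is.null(panel_path))
    stop("supply panel or panel_path")
  if (is.null(coefficients) && is.null(coefficients_path))
    stop("supply coefficients or coefficients_path")
  if (!all(thresholds >= 0 & thresholds <= 99))
    stop("thresholds must lie in [0, 99]")
  structure(list(panel = panel, coefficients = coefficients,
                 panel_path = panel_path,
                 coefficients_path = coefficients_path,
                 out_dir = out_dir, periods = periods,
                 thresholds = as.integer(thresholds),
                 primary_threshold = as.integer(primary_threshold),
                 impact_thresholds = as.integer(impact_thresholds),
                 bootstrap = bootstrap, smd_cut = smd_cut,
                 or_low = or_low, or_high = or_high,
                 ablation = isTRUE(ablation), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments (`panel` /
#' `coefficients` as file paths, `periods` as a list of
#' `{baseline_year, final_year}` pairs, `bootstrap` as
#' `{n_individuals, n_replicates, seed, ci_level}`).
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  periods <- if (is.null(y$periods)) drift_periods() else
    drift_periods(vapply(y$periods, `[[`, numeric(1), "baseline_year"),
                  vapply(y$periods, `[[`, numeric(1), "final_year"))
  boot <- if (is.null(y$bootstrap)) bootstrap_config(seed = y$seed %||% 1L) else
    bootstrap_config(y$bootstrap$n_individuals %||% 10000L,
                     y$bootstrap$n_replicates %||% 500L,
                     y$bootstrap$seed %||% (y$seed %||% 1L),
                     y$bootstrap$ci_level %||% 0.95)
  run_config(panel_path = y$panel, coefficients_path = y$coefficients,
             out_dir = y$out_dir, periods = periods,
             thresholds = y$thresholds %||% c(50L, 70L, 90L, 95L, 98L, 99L),
             primary_threshold = y$primary_threshold %||% 90L,
             impact_thresholds = y$impact_thresholds %||% c(90L, 98L, 99L),
             bootstrap = boot, smd_cut = y$smd_cut %||% 0.1,
             or_low = y$or_low %||% 0.5, or_high = y$or_high %||% 1.5,
             ablation = y$ablation %||% TRUE, seed = y$seed %||% 1L)
}

#' Per-year cohort descriptive summary
#'
#' @param panel a cohort panel.
#' @return data.frame: per year the row count, outcome prevalence,
#'   palliative-visit rate (when present) and every covariate prevalence.
#' @export
cohort_summary <- function(panel) {
  covs <- panel_covariates(panel)
  years <- sort(unique(panel$year))
  rows <- lapply(years, function(y) {
    sub <- panel[panel$year == y, , drop = FALSE]
    row <- data.frame(year = y, n = nrow(sub),
                      outcome_prevalence = mean(sub$outcome))
    if (!is.null(sub$palliative_visit))
      row$palliative_visit_rate <- mean(sub$palliative_visit)
    for (cl in covs) row[[cl]] <- mean(sub[[cl]])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the complete drift-monitoring pipeline
#'
#' Orchestrates scoring, year-by-threshold metrics (with calibration deciles
#' and AUC), period drift with bootstrap intervals and affected counts,
#' covariate-shift screening per period, optional ablation retraining, and
#' the quality-impact endpoints. Any stage failure aborts naming the stage.
#' When the panel lacks a `palliative_visit` column the impact stage is
#' skipped with a warning and the pipeline completes. With `out_dir` set,
#' report tables are written as CSV and everything as one machine-readable
#' JSON (`results.json`) whose header records the seed, configuration hash
#' and package version; two runs of the same configuration produce
#' byte-identical JSON.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list: `meta`, `cohort_summary`,
#'   `classification_rates`, `calibration`, `drift`, `shift`, `ablation`,
#'   `impact`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  panel <- stage("read_panel",
                 config$panel %||% read_panel(config$panel_path))
  panel <- stage("read_panel", validate_panel(panel))
  coefficients <- stage("read_coefficients",
                        config$coefficients %||%
                          read_coefficients(config$coefficients_path))
  # fingerprint the analytic configuration, not data objects or output paths
  hash_cfg <- config[setdiff(names(config),
                             c("panel", "coefficients", "out_dir"))]
  hash_cfg$coefficient_values <- coefficients$coefficient
  meta <- list(seed = config$seed, config_hash = config_hash(hash_cfg),
               package_version = as.character(packageVersion("candrift")),
               n_rows = nrow(panel), years = sort(unique(panel$year)))

  scored <- stage("score", score_panel(panel, coefficients))
  rates <- stage("metrics", do.call(rbind, lapply(config$thresholds,
    function(t) metrics_by_year(scored, t))))
  calib <- stage("metrics", {
    years <- sort(unique(scored$year))
    do.call(rbind, lapply(years, function(y) {
      sel <- scored$year == y
      cbind(year = y, calibration_by_decile(scored$raw_probability[sel],
                                            scored$outcome[sel]))
    }))
  })
  drift_tab <- stage("drift",
    drift_analysis(panel, coefficients, periods = config$periods,
                   threshold = config$primary_threshold,
                   bootstrap = config$bootstrap))
  shift_tab <- stage("shift", do.call(rbind,
    lapply(seq_len(nrow(config$periods)), function(i) {
      st <- shift_table(panel, coefficients,
                        config$periods$baseline_year[i],
                        config$periods$final_year[i])
      st <- screen_shifts(st, config$smd_cut, config$or_low, config$or_high)
      cbind(data.frame(period = config$periods$label[i],
                       stringsAsFactors = FALSE), st)
    })))
  ablation_tab <- if (config$ablation) stage("ablation", {
    comp <- shift_tab[shift_tab$period ==
      config$periods$label[which.max(config$periods$final_year -
                                       config$periods$baseline_year)], ]
    ablation_compare(panel, coefficients,
                     flagged = comp$covariate[comp$flagged],
                     periods = config$periods,
                     threshold = config$primary_threshold)
  }) else NULL
  impact_tab <- if (is.null(panel$palliative_visit)) {
    warning("panel has no palliative_visit column; impact stage skipped")
    NULL
  } else stage("impact",
    impact_trend(scored, thresholds = config$impact_thresholds))

  result <- list(meta = meta,
                 cohort_summary = stage("summary", cohort_summary(panel)),
                 classification_rates = rates, calibration = calib,
                 drift = drift_tab, shift = shift_tab,
                 ablation = ablation_tab, impact = impact_tab)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    header <- sprintf("# candrift %s seed=%d config=%s",
                      meta$package_version, meta$seed, meta$config_hash)
    for (nm in c("cohort_summary", "classification_rates", "calibration",
                 "drift", "shift", "ablation", "impact")) {
      if (is.null(result[[nm]])) next
      f <- file.path(config$out_dir, paste0(nm, ".csv"))
      writeLines(header, f)
      suppressWarnings(write.table(result[[nm]], f, sep = ",",
                                   row.names = FALSE, append = TRUE,
                                   qmethod = "double"))
    }
    jsonlite::write_json(result, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(result)
}
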
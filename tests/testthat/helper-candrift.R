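# independent oracles and small fixture builders

# all-pairs AUC with half-credit ties
oracle_auc <- function(p, y) {
  cases <- p[y == 1]
  controls <- p[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cases) * length(controls))
}

# Clopper-Pearson by direct inversion of binomial tail probabilities
oracle_clopper_pearson <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else
    uniroot(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# four-way tally by explicit loop
oracle_confusion <- function(flags, outcomes) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(flags)) {
    if (flags[i] == 1 && outcomes[i] == 1) tp <- tp + 1L
    else if (flags[i] == 1 && outcomes[i] == 0) fp <- fp + 1L
    else if (flags[i] == 0 && outcomes[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# percentile score by counting strictly smaller values
oracle_percentile <- function(x) {
  n <- length(x)
  vapply(x, function(v) floor(100 * sum(x < v) / n), numeric(1))
}

# minimal two-covariate simulation configuration
tiny_config <- function(n = 2000, years = 2020L, seed = 1L, ...) {
  covs <- data.frame(name = c("dx", "util0"),
                     category = c("diagnostic", "utilization"),
                     prevalence = c(0.3, 0.6))
  sim_config(n, years, covs, c(dx = log(2), util0 = log(0.5)),
             intercept = -2, seed = seed, ...)
}

# hand-built scored panel: can_score and outcomes set directly
manual_scored <- function(can_score, outcome, palliative_visit = NULL,
                          year = 2020L) {
  n <- length(can_score)
  df <- data.frame(patient_id = sprintf("M%03d", seq_len(n)), year = year,
                   outcome = outcome, can_score = as.integer(can_score))
  if (!is.null(palliative_visit)) df$palliative_visit <- palliative_visit
  df
}
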
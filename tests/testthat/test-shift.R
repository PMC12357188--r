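test_that("binary SMD uses the pooled-Bernoulli-variance form", {
  expect_equal(smd_from_prevalence(0.3, 0.3), 0)
  expect_equal(smd_from_prevalence(0.5, 0.6), 0.1 / sqrt(0.245))
  expect_equal(round(smd_from_prevalence(0.5, 0.6), 4), 0.2020)
  set.seed(2)
  a <- runif(20); b <- runif(20)
  expect_equal(smd_from_prevalence(a, b), -smd_from_prevalence(b, a))
  # degenerate equal prevalences define SMD as 0
  expect_equal(smd_from_prevalence(0, 0), 0)
  expect_equal(smd_from_prevalence(1, 1), 0)
})

test_that("panel smd matches the plug-in prevalences", {
  panel <- data.frame(patient_id = sprintf("A%02d", 1:10),
                      year = rep(c(2016L, 2020L), each = 5),
                      x = c(1, 0, 0, 0, 0, 1, 1, 1, 0, 0),
                      outcome = 0L)
  expect_equal(smd(panel, "x", 2016, 2020), smd_from_prevalence(0.2, 0.6))
  expect_error(smd(panel, "zz", 2016, 2020), "absent")
  expect_error(smd(panel, "x", 2016, 2021), "year absent")
})

test_that("screening is a pure, idempotent threshold rule", {
  rec <- data.frame(covariate = c("a", "b", "c", "d"),
                    category = "diagnostic",
                    smd = c(0, 0.15, -0.02, -0.12),
                    original_or = c(1, 1, 2.1, 0.5))
  out <- screen_shifts(rec)
  expect_equal(out$flagged_by_smd[match(c("a", "b", "c", "d"), out$covariate)],
               c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$flagged_by_or[match(c("a", "b", "c", "d"), out$covariate)],
               c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$flagged, out$flagged_by_smd | out$flagged_by_or)
  expect_equal(out$smd, out$smd[order(-abs(out$smd))])  # sorted by |smd|
  # idempotent and permutation-invariant
  expect_equal(screen_shifts(out), out)
  expect_equal(screen_shifts(rec[c(3, 1, 4, 2), ]), out)
  # boundary: or exactly 0.5 flags, smd exactly -0.1 does not (>= / < rules)
  b <- screen_shifts(data.frame(covariate = "e", category = NA,
                                smd = -0.1, original_or = 0.49))
  expect_false(b$flagged_by_smd)
  expect_true(b$flagged_by_or)
})

test_that("retrain recovers an intercept-only model in closed form", {
  cohort <- generate_cohort(tiny_config(n = 4000, seed = 17))
  panel <- cohort$panel
  fit <- retrain(panel, 2020, exclude = c("dx", "util0"))
  expect_equal(ct_intercept(fit), qlogis(mean(panel$outcome)),
               tolerance = 1e-6)
  # deterministic to numerical identity
  f1 <- retrain(panel, 2020, coefficients = cohort$coefficients)
  f2 <- retrain(panel, 2020, coefficients = cohort$coefficients)
  expect_identical(f1$coefficient, f2$coefficient)
  expect_equal(f1$category, cohort$coefficients$category)
})

test_that("retrain recovers generating coefficients without frailty", {
  covs <- data.frame(name = c("x1", "x2", "x3"),
                     category = c("diagnostic", "pharmacy", "utilization"),
                     prevalence = c(0.3, 0.5, 0.2))
  truth <- c(x1 = 0.8, x2 = -0.6, x3 = 0.4)
  cfg <- sim_config(30000, 2020L, covs, truth, intercept = -1.2,
                    frailty_sd = 0, seed = 23)
  out <- generate_cohort(cfg)
  fit <- retrain(out$panel, 2020)
  expect_true(all(abs(ct_beta(fit)[names(truth)] - truth) < 0.1))
  expect_lt(abs(ct_intercept(fit) - (-1.2)), 0.1)
})

test_that("retrain fails informatively on rank deficiency and bad input", {
  cohort <- generate_cohort(tiny_config(n = 1000, seed = 19))
  panel <- cohort$panel
  panel$dup <- panel$dx  # exact copy: collinear
  expect_error(retrain(panel, 2020), "collinear columns: dup")
  expect_error(retrain(panel, 1999), "train_year absent")
  expect_error(retrain(cohort$panel, 2020, exclude = "nope"),
               "not panel covariates")
})

test_that("excluding one dummy level drops its group siblings", {
  cfg <- default_scenario(n_patients = 3000, seed = 31)
  out <- generate_cohort(cfg)
  fit <- retrain(out$panel, 2016, exclude = "age_lt_55",
                 coefficients = out$coefficients)
  expect_false(any(c("age_lt_55", "age_55_64", "age_65_74") %in%
                     fit$covariate))
  fit_keep <- retrain(out$panel, 2016, exclude = "age_lt_55",
                      coefficients = out$coefficients,
                      expand_groups = FALSE)
  expect_true(all(c("age_55_64", "age_65_74") %in% fit_keep$covariate))
})

test_that("shift_table + screen recover injected shifts on a generated cohort", {
  cfg <- default_scenario(n_patients = 30000, seed = 37)
  out <- generate_cohort(cfg)
  st <- screen_shifts(shift_table(out$panel, out$coefficients, 2016, 2020))
  expect_setequal(st$covariate[st$flagged_by_smd], cfg$shifts$covariate)
  base_prev <- cfg$covariates$prevalence[match(cfg$shifts$covariate,
                                               cfg$covariates$name)]
  analytic <- smd_from_prevalence(base_prev, cfg$shifts$prevalence)
  got <- st$smd[match(cfg$shifts$covariate, st$covariate)]
  expect_true(all(abs(got - analytic) < 0.04))
})

test_that("ablation variants rerun the identical pipeline", {
  cohort <- generate_cohort(default_scenario(n_patients = 6000, seed = 41))
  periods <- drift_periods(2016L, 2020L)
  ab <- ablation_compare(cohort$panel, cohort$coefficients,
                         periods = periods, per_category = TRUE)
  # original variant reproduces drift_analysis exactly
  base <- drift_analysis(cohort$panel, cohort$coefficients, periods = periods)
  orig <- ab[ab$variant == "original", names(ab) != "variant"]
  rownames(orig) <- NULL
  expect_equal(orig, base)
  # one drift table per variant, incl. per-category exclusions
  expect_true(all(c("original", "retrain_excluding_flagged",
                    "retrain_full_2018", "retrain_full_2019") %in%
                    ab$variant))
  expect_gte(length(grep("^retrain_excluding_(?!flagged)", unique(ab$variant),
                         perl = TRUE)), 1)
  expect_true(all(table(ab$variant) == nrow(base)))
})

test_that("drift driven purely by falling prevalence survives ablation", {
  # no covariate shift scripted: only the outcome rate declines, so
  # excluding the OR-flagged covariates cannot remove the PPV drift
  covs <- data.frame(name = paste0("x", 1:8),
                     category = rep(c("diagnostic", "utilization",
                                      "pharmacy", "laboratory_vitals"), 2),
                     prevalence = c(0.2, 0.5, 0.15, 0.4, 0.3, 0.25, 0.6, 0.1))
  cfg <- sim_config(20000, c(2016L, 2020L), covs,
                    log(c(x1 = 2.2, x2 = 0.45, x3 = 1.3, x4 = 0.8,
                          x5 = 1.2, x6 = 0.7, x7 = 1.1, x8 = 0.9)),
                    prevalence_targets = c(0.05, 0.035), frailty_sd = 0.5,
                    seed = 47)
  out <- generate_cohort(cfg)
  periods <- drift_periods(2016L, 2020L)
  ab <- ablation_compare(out$panel, out$coefficients, periods = periods,
                         retrain_years = integer(0))
  ppv_orig <- ab$change_pts[ab$variant == "original" & ab$metric == "ppv"]
  ppv_excl <- ab$change_pts[ab$variant == "retrain_excluding_flagged" &
                              ab$metric == "ppv"]
  expect_lt(ppv_orig, 0)
  expect_lt(ppv_excl, 0)
  # ablation does not help: exclusion drift within the original's bootstrap CI
  ci <- drift_analysis(out$panel, out$coefficients, periods = periods,
                       bootstrap = bootstrap_config(10000, 200, seed = 53))
  expect_gte(ppv_excl, ci$ci_lower[ci$metric == "ppv"])
  expect_lte(ppv_excl, ci$ci_upper[ci$metric == "ppv"])
})
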
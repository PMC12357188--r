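test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(tiny_config(n = 500, years = 2019:2020, seed = 42))
  b <- generate_cohort(tiny_config(n = 500, years = 2019:2020, seed = 42))
  expect_identical(a, b)
  c_ <- generate_cohort(tiny_config(n = 500, years = 2019:2020, seed = 43))
  expect_false(identical(a$panel, c_$panel))
})

test_that("null model: prevalence ~ 0.5 and outcome independent of covariates", {
  covs <- data.frame(name = "x", category = "diagnostic", prevalence = 0.4)
  n <- 5000
  pvals <- vapply(1:10, function(s) {
    cfg <- sim_config(n, 2020L, covs, c(x = 0), intercept = qlogis(0.5),
                      seed = 100 + s)
    panel <- generate_cohort(cfg)$panel
    # binomial tolerance: 4 sd of a fair coin mean
    expect_lt(abs(mean(panel$outcome) - 0.5), 4 * sqrt(0.25 / n))
    suppressWarnings(chisq.test(table(panel$x, panel$outcome))$p.value)
  }, numeric(1))
  # independence by construction: ~5% rejections expected at alpha = 0.05
  expect_lte(sum(pvals < 0.05), 3)
})

test_that("frailty induces within-patient outcome correlation, zero frailty does not", {
  n <- 20000
  with_fr <- generate_cohort(tiny_config(n = n, years = 2019:2020, seed = 9,
                                         frailty_sd = 2))$panel
  y1 <- with_fr$outcome[with_fr$year == 2019]
  y2 <- with_fr$outcome[with_fr$year == 2020]
  expect_gt(cor(y1, y2), 0.05)
  no_fr <- generate_cohort(tiny_config(n = n, years = 2019:2020, seed = 9,
                                       frailty_sd = 0))$panel
  z1 <- no_fr$outcome[no_fr$year == 2019]
  z2 <- no_fr$outcome[no_fr$year == 2020]
  expect_lt(abs(cor(z1, z2)), 0.025)
})

test_that("per-year intercept calibration hits outcome prevalence targets", {
  covs <- data.frame(name = c("dx", "util0", "rx"),
                     category = c("diagnostic", "utilization", "pharmacy"),
                     prevalence = c(0.3, 0.6, 0.15))
  cfg <- sim_config(200000, c(2016L, 2020L), covs,
                    c(dx = log(2), util0 = log(0.5), rx = log(1.4)),
                    prevalence_targets = c(0.038, 0.030),
                    frailty_sd = 1, seed = 11)
  panel <- generate_cohort(cfg)$panel
  prev <- tapply(panel$outcome, panel$year, mean)
  expect_lt(abs(prev[["2016"]] - 0.038), 0.002)
  expect_lt(abs(prev[["2020"]] - 0.030), 0.002)
})

test_that("the ground-truth coefficient table reports what was used", {
  cfg <- tiny_config(n = 1000, years = 2019:2020, seed = 3,
                     prevalence_targets = c(0.05, 0.04))
  out <- generate_cohort(cfg)
  expect_s3_class(out$coefficients, "coefficient_table")
  expect_equal(ct_beta(out$coefficients), cfg$coefficients)
  yi <- attr(out$coefficients, "year_intercepts")
  expect_named(yi, c("2019", "2020"))
  expect_equal(ct_intercept(out$coefficients), unname(yi[1]))
  expect_lt(yi[["2020"]], yi[["2019"]])  # lower target, lower intercept
})

test_that("unreachable prevalence targets are reported", {
  cfg <- tiny_config(n = 200, seed = 5)
  cfg$prevalence_targets <- c("2020" = 1 - 1e-16)
  expect_error(generate_cohort(cfg), "unreachable prevalence target")
})

test_that("default scenario matches its documented structure", {
  cfg <- default_scenario(n_patients = 5000, seed = 2)
  expect_length(cfg$years, 5)
  expect_gte(nrow(cfg$covariates), 20)
  expect_setequal(unique(cfg$covariates$category),
                  c("demographic", "diagnostic", "laboratory_vitals",
                    "pharmacy", "utilization"))
  # scripted shifts all clear the large-shift threshold analytically
  base_prev <- cfg$covariates$prevalence[match(cfg$shifts$covariate,
                                               cfg$covariates$name)]
  expect_true(all(abs(smd_from_prevalence(base_prev,
                                          cfg$shifts$prevalence)) >= 0.1))
  # diagnostic and pharmacy covariates stay at baseline
  shifted_cat <- cfg$covariates$category[match(cfg$shifts$covariate,
                                               cfg$covariates$name)]
  expect_false(any(shifted_cat %in% c("diagnostic", "pharmacy")))
  expect_equal(unname(cfg$prevalence_targets[c(1, 5)]), c(0.038, 0.030))
  expect_true(all(diff(cfg$prevalence_targets) < 0))
  # grouped age dummies are mutually exclusive in the generated panel
  panel <- generate_cohort(cfg)$panel
  expect_true(all(panel$age_lt_55 + panel$age_55_64 + panel$age_65_74 <= 1))
  expect_true(all(table(panel$patient_id) == 5))
})

test_that("invalid configurations are rejected", {
  covs <- data.frame(name = "x", category = "diagnostic", prevalence = 0.4)
  expect_error(sim_config(10, c(2020, 2019), covs, c(x = 0)),
               "strictly increasing")
  expect_error(sim_config(10, 2020, covs, c(y = 0)), "named exactly")
  bad <- covs; bad$prevalence <- 1.2
  expect_error(sim_config(10, 2020, bad, c(x = 0)), "in \\(0,1\\)")
  expect_error(
    sim_config(10, 2020, covs, c(x = 0),
               shifts = data.frame(covariate = "zz", year = 2020,
                                   prevalence = 0.5)),
    "not in covariate spec")
})
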
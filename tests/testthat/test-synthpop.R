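# Synthetic cohort generator: validation, determinism, calibration,
# missingness, splitting.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(generator_config(target_subtype_fractions = c(0.5, 0.3, 0.3)),
               "target_subtype_fractions")
  expect_error(generator_config(missingness_rate = 0.25), "missingness_rate")
  expect_error(generator_config(target_prevalence = 1.2), "target_prevalence")
  cfg <- generator_config()
  cfg$glucose_model$sd_log_fpg <- -1
  expect_error(validate_generator_config(cfg), "glucose_model")
  cfg <- generator_config()
  cfg$glucose_model$rho <- 1.0
  expect_error(validate_generator_config(cfg), "rho")
})

test_that("n = 0 yields an empty table with the full column schema", {
  pop <- sample_population(generator_config(n_participants = 0))
  expect_equal(nrow(pop), 0L)
  expect_true(all(c("id", "age", "sbp", "rpr", "bmi", "whr", "whtr",
                    "fpg", "p2hpg", "hba1c", "dm_status", "subtype")
                  %in% names(pop)))
})

test_that("sampling is bit-identical for the same seed and differs across seeds", {
  a <- small_cohort(500, seed = 7)
  b <- small_cohort(500, seed = 7)
  c <- small_cohort(500, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$fpg, c$fpg))
})

test_that("realized prevalence and non-DM feature medians match the configuration", {
  cfg <- generator_config(n_participants = 8425, seed = 123)
  pop <- sample_population(cfg)
  p <- cfg$target_prevalence
  se <- sqrt(p * (1 - p) / nrow(pop))
  expect_lt(abs(mean(pop$dm_status) - p), 3 * se)
  nondm <- pop[!pop$dm_status, ]
  for (nm in c("age", "sbp", "rpr", "wc", "weight", "height")) {
    target <- cfg$feature_baselines[[nm]]$median
    expect_lt(abs(median(nondm[[nm]]) - target) / target, 0.05)
  }
})

test_that("glucose values are positive and anthropometric identities hold row-wise", {
  pop <- small_cohort(3000, seed = 5)
  expect_true(all(pop$fpg > 0) && all(pop$p2hpg > 0) && all(pop$hba1c > 0))
  expect_equal(pop$bmi, pop$weight / pop$height^2, tolerance = 1e-6)
  expect_equal(pop$whr, pop$wc / pop$hc, tolerance = 1e-6)
  expect_equal(pop$whtr, pop$wc / (pop$height * 100), tolerance = 1e-6)
  expect_true(all(pop$dm_status == (pop$subtype != "NON_DM")))
  # subtype counts among diabetics partition the diabetic stratum exactly
  counts <- table(pop$subtype[pop$dm_status])
  expect_identical(as.integer(sum(counts)), as.integer(sum(pop$dm_status)))
  expect_equal(sum(prop.table(counts)), 1)
})

test_that("with zero loadings and a z-free glucose model the DM and non-DM strata are exchangeable", {
  cfg <- generator_config(n_participants = 50000, seed = 31)
  for (nm in names(cfg$feature_baselines)) cfg$feature_baselines[[nm]]$loading <- 0
  cfg$glucose_model$z_load_fpg <- 0
  cfg$glucose_model$z_load_2hpg <- 0
  pop <- sample_population(cfg)
  for (nm in c("age", "rpr", "sbp")) {
    gap <- median(pop[[nm]][pop$dm_status]) - median(pop[[nm]][!pop$dm_status])
    sd_nm <- (cfg$feature_baselines[[nm]]$iqr[2] -
              cfg$feature_baselines[[nm]]$iqr[1]) / 1.349
    # Monte-Carlo error of a median difference at n_dm ~ 6200
    expect_lt(abs(gap), 4 * 1.25 * sd_nm / sqrt(sum(pop$dm_status)))
  }
})

test_that("raising the post-load glucose mean raises realized prevalence", {
  prev <- vapply(c(-0.1, 0, 0.1), function(shift) {
    cfg <- generator_config(n_participants = 30000, seed = 77)
    cfg$glucose_model$mu_log_2hpg <- cfg$glucose_model$mu_log_2hpg + shift
    mean(sample_population(cfg)$dm_status)
  }, 0)
  expect_true(all(diff(prev) > 0))
})

test_that("calibration reaches requested prevalence and subtype split at n = 50,000", {
  cfg <- calibrate_generator(generator_config(),
                             targets = list(prevalence = 0.124,
                                            subtype_fractions = c(0.41, 0.28, 0.31)),
                             n_calibration = 50000, seed = 9)
  check <- cfg; check$n_participants <- 50000; check$seed <- 10
  pop <- sample_population(check)
  expect_lt(abs(mean(pop$dm_status) - 0.124), 0.01)
  fr <- prop.table(table(pop$subtype[pop$dm_status]))
  expect_lt(abs(fr[["ISOLATED_POSTLOAD"]] - 0.41), 0.03)
  expect_lt(abs(fr[["ISOLATED_FASTING"]] - 0.28), 0.03)
  expect_lt(abs(fr[["COMBINED"]] - 0.31), 0.03)
})

test_that("recalibrating to the current targets is a fixed point", {
  cfg <- generator_config()
  out <- calibrate_generator(cfg, n_calibration = 50000, seed = 4)
  expect_equal(out$glucose_model$mu_log_fpg, cfg$glucose_model$mu_log_fpg,
               tolerance = 1e-4)
  expect_equal(out$glucose_model$mu_log_2hpg, cfg$glucose_model$mu_log_2hpg,
               tolerance = 1e-4)
  expect_equal(out$glucose_model$rho, cfg$glucose_model$rho, tolerance = 1e-3)
})

test_that("an extreme combined-subtype target fails with diagnostics", {
  expect_error(
    calibrate_generator(generator_config(),
                        targets = list(prevalence = 0.124,
                                       subtype_fractions = c(0.005, 0.005, 0.99))),
    "calibration failure")
})

test_that("the joint-exceedance kernel matches a Monte-Carlo oracle", {
  r <- 0.7; za <- 1.2; zb <- 0.9
  analytic <- dmscreen:::bivariate_upper_tail(za, zb, r)
  mc <- withr::with_seed(11, {
    x <- rnorm(4e5); y <- r * x + sqrt(1 - r^2) * rnorm(4e5)
    mean(x >= za & y >= zb)
  })
  expect_equal(analytic, mc, tolerance = 0.02)
})

test_that("missingness injection is MCAR at the requested rate and spares labs", {
  pop <- small_cohort(10000, seed = 2)
  out <- inject_missingness(pop, 0.1, seed = 3)
  for (nm in c("age", "rpr", "sbp", "wc")) {
    expect_gte(mean(is.na(out[[nm]])), 0.09)
    expect_lte(mean(is.na(out[[nm]])), 0.11)
  }
  expect_false(anyNA(out$fpg) || anyNA(out$p2hpg) || anyNA(out$hba1c) ||
                 anyNA(out$dm_status))
  expect_identical(out, inject_missingness(pop, 0.1, seed = 3))
  expect_identical(inject_missingness(pop, 0), pop)
  expect_error(inject_missingness(pop, 0.25), "20%")
})

test_that("the development/testing split is exact, disjoint and seeded", {
  pop <- small_cohort(8425, seed = 1)
  sp <- split_dev_test(pop, 0.6, seed = 5)
  expect_equal(nrow(sp$dev), 5055L)
  expect_equal(nrow(sp$test), 3370L)
  expect_length(intersect(sp$dev$id, sp$test$id), 0)
  expect_setequal(c(sp$dev$id, sp$test$id), pop$id)
  sp2 <- split_dev_test(pop, 0.6, seed = 5)
  expect_identical(sp$dev$id, sp2$dev$id)
  tiny <- split_dev_test(small_cohort(2, seed = 3), 0.5, seed = 1)
  expect_equal(nrow(tiny$dev), 1L)
  expect_equal(nrow(tiny$test), 1L)
  expect_error(split_dev_test(small_cohort(1, seed = 3), 0.5), "2 rows")
})

test_that("population tables round-trip through CSV losslessly", {
  pop <- small_cohort(100, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(as.data.frame(back), as.data.frame(pop))
})
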
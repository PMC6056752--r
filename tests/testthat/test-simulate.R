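test_that("the generator is a pure, seed-deterministic function of config", {
  cfg <- simulation_config(seed = 99)
  a <- simulate_peak_areas(cfg)
  b <- simulate_peak_areas(cfg)
  expect_identical(a, b)
  expect_identical(simulate_heterogeneity(cfg), simulate_heterogeneity(cfg))
  expect_identical(simulate_oxidation(cfg), simulate_oxidation(cfg))
  # different seeds differ
  expect_false(identical(a, simulate_peak_areas(simulation_config(seed = 100))))
  # the caller's RNG stream is untouched
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(simulate_peak_areas(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("the written CSV is byte-identical across repeat runs", {
  cfg <- simulation_config(seed = 7)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_peak_areas(simulate_peak_areas(cfg), f1)
  write_peak_areas(simulate_peak_areas(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

zero_noise_config <- function(...) {
  simulation_config(seed = 1, calibration_cv_pct = 0,
                    qc_cv_pct = c(LLOQ = 0, LQC = 0, MQC = 0, HQC = 0),
                    istd_cv_pct = 0, heterogeneity_cv_pct = 0,
                    oxidation_cv_pct = 0, ...)
}

test_that("with zero CV the areas sit exactly on the true line", {
  cfg <- zero_noise_config()
  meas <- simulate_peak_areas(cfg)
  cal <- meas[meas$role == "calibrator", ]
  resp <- cal$analyte_area / cal$istd_area
  expect_equal(resp, cfg$slope * cal$nominal_conc + cfg$intercept,
               tolerance = 1e-12)
  fit <- fit_calibration(cal)
  expect_equal(fit$slope, cfg$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, cfg$intercept, tolerance = 1e-10)
})

test_that("the simulated batch covers the full validation design", {
  cfg <- simulation_config(seed = 3)
  meas <- simulate_peak_areas(cfg)
  expect_equal(sum(meas$role == "calibrator"), 10)
  expect_equal(sum(meas$role == "qc"),
               cfg$qc$runs * cfg$qc$replicates_per_run *
                 length(cfg$qc$levels))
  expect_true(all(c("blank", "zero") %in% meas$role))
  expect_equal(round_half_up(min(meas$nominal_conc, na.rm = TRUE), 3),
               0.195)
})

test_that("variant mixtures recover their shares", {
  cfg <- zero_noise_config()
  h <- simulate_heterogeneity(cfg)
  content <- heterogeneity_content(setNames(h$normalized, h$variant))
  # percent-of-max from the default 0.705/0.261/0.034 mixture
  expect_equal(content$percent_of_max, c(100, 37.0, 4.8), tolerance = 0.01)
  expect_equal(content$share_pct, 100 * cfg$heterogeneity_shares,
               tolerance = 1e-9, ignore_attr = TRUE)
  # a single present variant leaves the others not-detected
  one <- zero_noise_config(heterogeneity_shares = c(a = 1, b = 0, c = 0))
  h1 <- simulate_heterogeneity(one)
  expect_equal(is.na(h1$normalized), c(FALSE, TRUE, TRUE))
})

test_that("oxidation-state simulation mirrors the ratio analysis", {
  cfg <- zero_noise_config()
  ox <- simulate_oxidation(cfg)
  # fully reduced control: dimer below the detection threshold
  expect_true(is.na(ox$dimer[ox$condition == "control"]))
  r <- oxidation_ratio(ox, monomer_reference = "control",
                       dimer_reference = "h2o2")
  expect_equal(r$monomer_pct[r$condition == "h2o2"], 0.26,
               tolerance = 1e-9)
  # ratios do not depend on the common response factor
  big <- zero_noise_config(response_factor = 50)
  r2 <- oxidation_ratio(simulate_oxidation(big),
                        monomer_reference = "control",
                        dimer_reference = "h2o2")
  expect_equal(r2$monomer_pct, r$monomer_pct, tolerance = 1e-9)
})

test_that("config validation rejects inconsistent inputs", {
  expect_error(simulation_config(heterogeneity_shares = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(simulation_config(qc_cv_pct = c(LLOQ = 5)), "named after")
  expect_error(simulation_config(istd_cv_pct = -1), "non-negative")
  expect_error(simulation_config(oxidation_fractions = list(
    control = c(monomer = 1.2, dimer = 0))), "0, 1")
})

test_that("simulate-quantify-validate round trip passes on a typical seed", {
  res <- quantify_study(simulate_peak_areas(simulation_config(seed = 2026)))
  expect_s3_class(res$curve, "calibration_curve")
  expect_true(res$verdict$overall_pass)
  expect_true(res$selectivity$pass)
  pooled <- res$report$table[res$report$table$run == "pooled", ]
  expect_true(all(abs(pooled$accuracy_pct - 100) < 20))
})
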
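test_that("run statistics use sample SD, CV and accuracy conventions", {
  st <- run_statistics(c(10, 10, 10, 10, 10), nominal = 8)
  expect_equal(st$sd, 0)
  expect_equal(st$cv_pct, 0)
  expect_equal(st$accuracy_pct, 125)
  st2 <- run_statistics(c(9, 10, 11), nominal = 10)
  expect_equal(st2$mean, 10)
  expect_equal(st2$sd, 1)
  expect_equal(st2$cv_pct, 10)
  expect_equal(st2$accuracy_pct, 100)
  # a zero mean makes the CV non-computable, not infinite
  expect_true(is.na(run_statistics(c(-1, 1), nominal = 1)$cv_pct))
  expect_error(run_statistics(5, 10), "2 replicates")
  expect_error(run_statistics(c(1, 2), 0), "positive")
})

simulated_report <- function(seed = 1, design = qc_design()) {
  set.seed(seed)
  conc <- do.call(rbind, lapply(names(design$levels), function(lv) {
    nominal <- design$levels[[lv]]
    data.frame(run_id = rep(sprintf("run%d", seq_len(design$runs)),
                            each = design$replicates_per_run),
               level = lv,
               conc = nominal * rlnorm(design$runs *
                                         design$replicates_per_run,
                                       0, 0.08))
  }))
  validation_report(conc, design)
}

test_that("report cells recompute from their own mean/SD/nominal", {
  rep <- simulated_report(31)
  t <- rep$table
  expect_equal(t$cv_pct, 100 * t$sd / t$mean, tolerance = 1e-12)
  expect_equal(t$accuracy_pct, 100 * t$mean / t$nominal,
               tolerance = 1e-12)
  # recomputing from the printed (3 s.f.) mean/SD/nominal reproduces the
  # printed CV and accuracy cells to within last-digit rounding
  printed_cv <- 100 * signif_half_up(t$sd) / signif_half_up(t$mean)
  expect_equal(signif_half_up(printed_cv), signif_half_up(t$cv_pct),
               tolerance = 0.01)
  printed_acc <- 100 * signif_half_up(t$mean) / t$nominal
  expect_equal(signif_half_up(printed_acc),
               signif_half_up(t$accuracy_pct), tolerance = 0.01)
})

test_that("pooled rows aggregate all individual values", {
  rep <- simulated_report(32)
  t <- rep$table
  pooled <- t[t$run == "pooled", ]
  expect_equal(pooled$n,
               rep(rep$design$runs * rep$design$replicates_per_run, 4))
  for (lv in pooled$level) {
    runs <- t[t$run != "pooled" & t$level == lv, ]
    # equal run sizes: pooled mean is the mean of run means
    expect_equal(pooled$mean[pooled$level == lv], mean(runs$mean),
                 tolerance = 1e-12)
  }
})

test_that("guideline verdicts apply the 15/20% rules inclusively", {
  design <- qc_design()
  t_pass <- data.frame(run_id = "run1", level = rep(names(design$levels),
                                                    each = 2),
                       conc = rep(design$levels, each = 2))
  rep <- validation_report(t_pass, design)
  v <- guideline_check(rep)
  expect_true(v$overall_pass)

  # 21-point bias at the LQC fails
  biased <- t_pass
  biased$conc[biased$level == "LQC"] <- 0.79 * design$levels[["LQC"]]
  v2 <- guideline_check(validation_report(biased, design))
  expect_false(v2$overall_pass)
  expect_false(all(v2$cells$pass[v2$cells$level == "LQC"]))

  # CV exactly at the 15% boundary passes (and 20% at the LLOQ)
  m <- design$levels[["MQC"]]
  vals <- m + c(-1, 1) * m * 0.15 / sqrt(2)
  expect_equal(100 * sd(vals) / mean(vals), 15, tolerance = 1e-9)
  boundary <- t_pass
  boundary$conc[boundary$level == "MQC"] <- vals
  v3 <- guideline_check(validation_report(boundary, design))
  expect_true(all(v3$cells$pass[v3$cells$level == "MQC"]))
})

test_that("a report without the LLOQ level is rejected", {
  design <- qc_design()
  conc <- data.frame(run_id = "run1",
                     level = rep(c("LQC", "MQC", "HQC"), each = 2),
                     conc = rep(design$levels[-1], each = 2))
  expect_error(validation_report(conc, design), "LLOQ")
})

test_that("tightening thresholds never converts a fail into a pass", {
  rep <- simulated_report(33)
  loose <- guideline_check(rep, thresholds = guideline_thresholds())
  tight <- guideline_check(rep, thresholds = guideline_thresholds(
    accuracy_tol_pct = 10, accuracy_tol_lloq_pct = 12,
    cv_max_pct = 8, cv_max_lloq_pct = 10))
  expect_true(all(which(tight$cells$pass) %in% which(loose$cells$pass)))
  if (!loose$overall_pass) expect_false(tight$overall_pass)
})

test_that("calibration acceptance needs 75% of levels and at least six", {
  cal <- data.frame(role = "calibrator",
                    nominal_conc = calibration_levels(),
                    istd_area = 1e5)
  cal$analyte_area <- cal$istd_area * 0.02 * cal$nominal_conc
  curve <- fit_calibration(cal)
  design <- qc_design()
  conc <- data.frame(run_id = "run1",
                     level = rep(names(design$levels), each = 2),
                     conc = rep(design$levels, each = 2))
  rep <- validation_report(conc, design)
  expect_true(guideline_check(rep, curve)$calibration_pass)
  # force most levels out of tolerance via a fake failing level table
  bad <- curve
  bad$levels$pass[1:6] <- FALSE
  v <- guideline_check(rep, bad)
  expect_false(v$calibration_pass)
  expect_false(v$overall_pass)
})

test_that("selectivity compares blanks against the LLOQ inclusively", {
  lloq <- data.frame(analyte_area = c(100, 100), istd_area = c(1000, 1000))
  clean <- data.frame(analyte_area = 0, istd_area = 1)
  expect_true(selectivity_check(clean, lloq)$pass)
  dirty <- data.frame(analyte_area = 100, istd_area = 1000)
  expect_false(selectivity_check(dirty, lloq)$pass)
  boundary <- data.frame(analyte_area = 20, istd_area = 50)
  expect_true(selectivity_check(boundary, lloq)$pass)  # exactly 20% / 5%
  expect_error(selectivity_check(clean, lloq[0, ]), "LLOQ")
})
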
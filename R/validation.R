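#' Quality-control design of a validation study
#'
#' Nominal QC concentrations and replication layout for a precision/accuracy
#' validation: an LLOQ level plus low/middle/high QC levels, measured as
#' `replicates_per_run` replicates in each of `runs` analytical runs.
#'
#' @param levels Named, strictly increasing, positive numeric vector of
#'   nominal concentrations in ug/mL. The first level is treated as the
#'   LLOQ. Defaults are the set concentrations of a 0.195-100 ug/mL
#'   Fc-fusion protein assay.
#' @param replicates_per_run Replicates per run (default 5).
#' @param runs Number of runs (default 3).
#' @return An object of class `qc_design`.
#' @export
qc_design <- function(levels = c(LLOQ = 0.195, LQC = 0.586, MQC = 9.38,
                                 HQC = 80.0),
                      replicates_per_run = 5L, runs = 3L) {
  if (is.null(names(levels)) || any(!nzchar(names(levels)))) {
    stop("levels must be named", call. = FALSE)
  }
  if (any(levels <= 0) || any(diff(levels) <= 0)) {
    stop("levels must be positive and strictly increasing", call. = FALSE)
  }
  replicates_per_run <- as.integer(replicates_per_run)
  runs <- as.integer(runs)
  stopifnot(replicates_per_run >= 1L, runs >= 1L)
  structure(list(levels = levels, replicates_per_run = replicates_per_run,
                 runs = runs),
            class = "qc_design")
}

#' Mean, SD, CV and accuracy of replicate concentrations
#'
#' The cell statistics of a precision/accuracy table: arithmetic mean,
#' sample SD (n-1 denominator), precision as CV% = 100*SD/mean, and
#' accuracy% = 100*mean/nominal.
#'
#' @param values Back-calculated concentrations (ug/mL), length >= 2.
#' @param nominal Positive nominal concentration (ug/mL).
#' @return List with `n`, `mean`, `sd`, `cv_pct` (`NA` when the mean is
#'   zero, i.e. not computable), and `accuracy_pct`. Values are unrounded;
#'   reports round to 3 significant figures at print time.
#' @export
run_statistics <- function(values, nominal) {
  if (length(values) < 2L) stop("need >= 2 replicates", call. = FALSE)
  if (!is.finite(nominal) || nominal <= 0) {
    stop("nominal must be positive", call. = FALSE)
  }
  m <- mean(values)
  s <- sd(values)
  list(n = length(values), mean = m, sd = s,
       cv_pct = if (m == 0) NA_real_ else 100 * s / m,
       accuracy_pct = 100 * m / nominal)
}

#' Precision/accuracy validation report
#'
#' Builds the per-run and pooled mean/SD/CV/accuracy table of a validation
#' study from back-calculated QC concentrations. Pooled statistics are
#' computed from all `runs * replicates_per_run` individual values, not from
#' per-run summaries.
#'
#' @param concentrations Data.frame with columns `run_id`, `level` (label
#'   matching `design$levels` names), and `conc` (ug/mL).
#' @param design A [qc_design()].
#' @return Object of class `validation_report` holding `table` (columns
#'   `run`, `level`, `nominal`, `n`, `mean`, `sd`, `cv_pct`,
#'   `accuracy_pct`; `run == "pooled"` rows last) and `design`.
#' @export
validation_report <- function(concentrations, design = qc_design()) {
  stopifnot(inherits(design, "qc_design"),
            all(c("run_id", "level", "conc") %in% names(concentrations)))
  missing_lv <- setdiff(names(design$levels),
                        unique(concentrations$level))
  if (length(missing_lv)) {
    stop(sprintf("no measurements for level(s): %s",
                 paste(missing_lv, collapse = ", ")), call. = FALSE)
  }
  runs <- sort(unique(concentrations$run_id))
  cells <- list()
  for (lv in names(design$levels)) {
    nominal <- design$levels[[lv]]
    lv_data <- concentrations[concentrations$level == lv, , drop = FALSE]
    for (r in runs) {
      v <- lv_data$conc[lv_data$run_id == r]
      st <- run_statistics(v, nominal)
      cells[[length(cells) + 1L]] <- data.frame(
        run = as.character(r), level = lv, nominal = nominal, n = st$n,
        mean = st$mean, sd = st$sd, cv_pct = st$cv_pct,
        accuracy_pct = st$accuracy_pct, stringsAsFactors = FALSE)
    }
    st <- run_statistics(lv_data$conc, nominal)
    cells[[length(cells) + 1L]] <- data.frame(
      run = "pooled", level = lv, nominal = nominal, n = st$n,
      mean = st$mean, sd = st$sd, cv_pct = st$cv_pct,
      accuracy_pct = st$accuracy_pct, stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, cells)
  rownames(table) <- NULL
  structure(list(table = table, design = design),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  t <- x$table
  for (col in c("mean", "sd", "cv_pct", "accuracy_pct")) {
    t[[col]] <- signif_half_up(t[[col]])
  }
  print.data.frame(t, row.names = FALSE)
  invisible(x)
}

#' Guideline acceptance thresholds
#'
#' Default thresholds follow common bioanalytical method validation
#' guidance for chromatographic assays: accuracy within +/-15% of nominal
#' and precision CV <= 15% (both relaxed to 20% at the LLOQ); at least 75%
#' of calibration levels, and no fewer than 6, back-calculating within the
#' same tolerances; boundary values pass (comparisons are inclusive).
#'
#' @param accuracy_tol_pct,accuracy_tol_lloq_pct Allowed accuracy bias (%).
#' @param cv_max_pct,cv_max_lloq_pct Maximum CV (%).
#' @param calibration_fraction Minimum fraction of calibration levels in
#'   tolerance.
#' @param calibration_min_levels Minimum number of calibration levels in
#'   tolerance.
#' @param blank_analyte_max_pct Maximum blank analyte response, as percent
#'   of the mean LLOQ analyte response (selectivity).
#' @param blank_istd_max_pct Maximum blank ISTD-channel response, as percent
#'   of the mean ISTD response (selectivity).
#' @return Named list of thresholds.
#' @export
guideline_thresholds <- function(accuracy_tol_pct = 15,
                                 accuracy_tol_lloq_pct = 20,
                                 cv_max_pct = 15,
                                 cv_max_lloq_pct = 20,
                                 calibration_fraction = 0.75,
                                 calibration_min_levels = 6L,
                                 blank_analyte_max_pct = 20,
                                 blank_istd_max_pct = 5) {
  list(accuracy_tol_pct = accuracy_tol_pct,
       accuracy_tol_lloq_pct = accuracy_tol_lloq_pct,
       cv_max_pct = cv_max_pct, cv_max_lloq_pct = cv_max_lloq_pct,
       calibration_fraction = calibration_fraction,
       calibration_min_levels = as.integer(calibration_min_levels),
       blank_analyte_max_pct = blank_analyte_max_pct,
       blank_istd_max_pct = blank_istd_max_pct)
}

#' Apply guideline acceptance rules to a validation report
#'
#' Each cell (run x level and pooled x level) passes if its accuracy bias
#' and CV are within tolerance (wider tolerance at the LLOQ). When a
#' calibration curve is supplied, the calibration passes if at least
#' `calibration_fraction` of its levels — and no fewer than
#' `calibration_min_levels` — back-calculate within tolerance. The overall
#' verdict is the conjunction. All comparisons are boundary-inclusive.
#'
#' @param report A [validation_report()].
#' @param curve Optional [fit_calibration()] object.
#' @param thresholds A [guideline_thresholds()] list.
#' @return Object of class `guideline_verdict` with `cells` (the report
#'   table plus `pass_accuracy`, `pass_cv`, `pass`), `calibration_pass`
#'   (`NA` when no curve given), and `overall_pass`.
#' @export
guideline_check <- function(report, curve = NULL,
                            thresholds = guideline_thresholds()) {
  stopifnot(inherits(report, "validation_report"))
  t <- report$table
  lloq_label <- names(report$design$levels)[1L]
  if (!lloq_label %in% t$level) {
    stop("report lacks the LLOQ level", call. = FALSE)
  }
  is_lloq <- t$level == lloq_label
  acc_tol <- ifelse(is_lloq, thresholds$accuracy_tol_lloq_pct,
                    thresholds$accuracy_tol_pct)
  cv_max <- ifelse(is_lloq, thresholds$cv_max_lloq_pct,
                   thresholds$cv_max_pct)
  t$pass_accuracy <- abs(t$accuracy_pct - 100) <= acc_tol
  t$pass_cv <- !is.na(t$cv_pct) & t$cv_pct <= cv_max
  t$pass <- t$pass_accuracy & t$pass_cv
  calibration_pass <- NA
  if (!is.null(curve)) {
    stopifnot(inherits(curve, "calibration_curve"))
    n_ok <- sum(curve$levels$pass)
    calibration_pass <- n_ok >= thresholds$calibration_min_levels &&
      n_ok >= thresholds$calibration_fraction * nrow(curve$levels)
  }
  overall <- all(t$pass) && !isFALSE(calibration_pass)
  structure(list(cells = t, calibration_pass = calibration_pass,
                 overall_pass = overall, thresholds = thresholds),
            class = "guideline_verdict")
}

#' @export
print.guideline_verdict <- function(x, ...) {
  cat(sprintf("<guideline_verdict> overall: %s\n",
              if (x$overall_pass) "PASS" else "FAIL"))
  if (!is.na(x$calibration_pass)) {
    cat(sprintf("calibration: %s\n",
                if (x$calibration_pass) "PASS" else "FAIL"))
  }
  bad <- x$cells[!x$cells$pass, c("run", "level", "cv_pct", "accuracy_pct")]
  if (nrow(bad)) {
    cat("failing cells:\n")
    print.data.frame(bad, row.names = FALSE)
  }
  invisible(x)
}

#' Selectivity check against blank interference
#'
#' A selective assay shows no material signal in analyte-free matrix: every
#' blank's analyte-channel response must not exceed
#' `blank_analyte_max_pct`% of the mean LLOQ analyte response, and every
#' blank's ISTD-channel response must not exceed `blank_istd_max_pct`% of
#' the mean ISTD response of the LLOQ samples. Boundaries are inclusive.
#'
#' @param blank Data.frame of blank measurements (`analyte_area`,
#'   `istd_area`).
#' @param lloq Data.frame of LLOQ-level measurements (`analyte_area`,
#'   `istd_area`).
#' @param thresholds A [guideline_thresholds()] list.
#' @return List with `pass`, `analyte_pct` and `istd_pct` (worst-case blank
#'   responses as percents of the LLOQ references).
#' @export
selectivity_check <- function(blank, lloq,
                              thresholds = guideline_thresholds()) {
  if (is.null(lloq) || !nrow(lloq)) stop("no LLOQ measurements",
                                         call. = FALSE)
  if (is.null(blank) || !nrow(blank)) stop("no blank measurements",
                                           call. = FALSE)
  analyte_pct <- 100 * max(blank$analyte_area) / mean(lloq$analyte_area)
  istd_pct <- 100 * max(blank$istd_area) / mean(lloq$istd_area)
  list(pass = analyte_pct <= thresholds$blank_analyte_max_pct &&
         istd_pct <= thresholds$blank_istd_max_pct,
       analyte_pct = analyte_pct, istd_pct = istd_pct)
}
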
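#' Configuration for the synthetic MRM peak-area generator
#'
#' Defines the study conditions the generator emulates: an ISTD-normalized
#' linear response with multiplicative lognormal noise, a 10-point 2-fold
#' calibration series from 100 ug/mL, QC replicates over three runs, an
#' N-terminal variant mixture, and monomer/dimer oxidation states with a
#' not-detected threshold.
#'
#' @param seed Integer RNG seed; the generator is a pure function of its
#'   config (identical config gives identical output).
#' @param slope,intercept True calibration line on the normalized-response
#'   scale (defaults 0.02 and 0; only recovery of these is asserted
#'   anywhere, never their absolute values).
#' @param calibration_top,calibration_levels,calibration_fold Calibration
#'   series design (defaults: 10 levels, 2-fold from 100 ug/mL).
#' @param calibration_cv_pct Calibrator area CV in percent (default 5).
#' @param qc A [qc_design()] (defaults: 0.195/0.586/9.38/80 ug/mL, 3 runs of
#'   5 replicates).
#' @param qc_cv_pct Named per-level QC CVs in percent. Defaults mirror the
#'   pooled precision a validated Fc-fusion assay shows: about 9% at the
#'   LLOQ falling to 5-6% at the higher QC levels.
#' @param istd_mean,istd_cv_pct ISTD peak-area scale and CV (defaults 1e5
#'   and 5%).
#' @param blank_analyte_frac,blank_istd_frac Blank-channel background as a
#'   fraction of the LLOQ analyte signal and of the ISTD level (defaults
#'   0.02 and 0.01).
#' @param heterogeneity_shares True variant shares (sum 1); defaults to the
#'   three-variant N-terminal mixture scenario with the main form at ~70%.
#' @param heterogeneity_cv_pct Variant intensity CV (default 5).
#' @param oxidation_fractions Named list of `c(monomer=, dimer=)` true
#'   fractions per condition; defaults to an untreated control and a
#'   near-complete peroxide oxidation.
#' @param oxidation_cv_pct Oxidation intensity CV (default 5).
#' @param response_factor Common normalized-response scale for the
#'   ratio-type simulations (default 1).
#' @param nd_threshold Normalized intensity below which a species reports
#'   not-detected (default 1e-3).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              slope = 0.02, intercept = 0,
                              calibration_top = 100,
                              calibration_levels = 10L,
                              calibration_fold = 2,
                              calibration_cv_pct = 5,
                              qc = qc_design(),
                              qc_cv_pct = c(LLOQ = 9, LQC = 6, MQC = 5,
                                            HQC = 6),
                              istd_mean = 1e5, istd_cv_pct = 5,
                              blank_analyte_frac = 0.02,
                              blank_istd_frac = 0.01,
                              heterogeneity_shares = c(
                                MHVAQPAVVLASSR = 0.705,
                                AMHVAQPAVVLASSR = 0.261,
                                MAMHVAQPAVVLASSR = 0.034),
                              heterogeneity_cv_pct = 5,
                              oxidation_fractions = list(
                                control = c(monomer = 1, dimer = 0),
                                h2o2 = c(monomer = 0.0026,
                                         dimer = 0.9974)),
                              oxidation_cv_pct = 5,
                              response_factor = 1,
                              nd_threshold = 1e-3) {
  stopifnot(inherits(qc, "qc_design"))
  if (!setequal(names(qc_cv_pct), names(qc$levels))) {
    stop("qc_cv_pct must be named after the QC levels", call. = FALSE)
  }
  if (any(c(calibration_cv_pct, qc_cv_pct, istd_cv_pct,
            heterogeneity_cv_pct, oxidation_cv_pct) < 0)) {
    stop("CVs must be non-negative", call. = FALSE)
  }
  if (abs(sum(heterogeneity_shares) - 1) > 1e-8) {
    stop("heterogeneity_shares must sum to 1", call. = FALSE)
  }
  for (fr in oxidation_fractions) {
    if (any(fr < 0 | fr > 1)) {
      stop("oxidation fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "simulation_config")
}

# Multiplicative lognormal noise with unit mean and the given CV (percent).
lognormal_noise <- function(n, cv_pct) {
  if (cv_pct == 0) return(rep(1, n))
  cv <- cv_pct / 100
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Run `expr` with the RNG seeded from (seed, stream) without disturbing the
# caller's RNG state; streams decouple the three generators so adding
# measurements to one never shifts another.
with_sim_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% 2147483000L + stream)
  expr
}

#' Simulate ISTD-normalized MRM peak areas
#'
#' Generates the peak-area table of a complete validation batch: blanks,
#' zero samples, a serial-dilution calibration series, and QC replicates
#' over multiple runs. Analyte areas follow
#' `istd_area * (slope * conc + intercept) * eps` with lognormal `eps` of
#' unit mean at the level's CV; blank channels draw scaled-down background
#' signal.
#'
#' @param config A [simulation_config()].
#' @return Data.frame of measurements with columns `sample_id`, `run_id`,
#'   `replicate`, `role` (`blank`/`zero`/`calibrator`/`qc`), `level`,
#'   `transition_label`, `analyte_area`, `istd_area`, `nominal_conc`.
#' @export
simulate_peak_areas <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_sim_seed(config$seed, 1L, {
    rows <- list()
    istd <- function(n) config$istd_mean * lognormal_noise(n,
                                                           config$istd_cv_pct)
    lloq_conc <- config$calibration_top /
      config$calibration_fold^(config$calibration_levels - 1L)
    lloq_signal <- config$slope * lloq_conc + config$intercept
    emit <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
      ..., stringsAsFactors = FALSE)
    for (i in 1:2) {
      emit(sample_id = sprintf("blank_%d", i), run_id = "run1",
           replicate = i, role = "blank", level = NA_character_,
           transition_label = "analyte",
           analyte_area = config$istd_mean * lloq_signal *
             config$blank_analyte_frac * lognormal_noise(1L, 25),
           istd_area = config$istd_mean * config$blank_istd_frac *
             lognormal_noise(1L, 25),
           nominal_conc = NA_real_)
      emit(sample_id = sprintf("zero_%d", i), run_id = "run1",
           replicate = i, role = "zero", level = NA_character_,
           transition_label = "analyte",
           analyte_area = config$istd_mean * lloq_signal *
             config$blank_analyte_frac * lognormal_noise(1L, 25),
           istd_area = istd(1L), nominal_conc = NA_real_)
    }
    cal <- calibration_levels(config$calibration_top,
                              config$calibration_levels,
                              config$calibration_fold)
    for (i in seq_along(cal)) {
      ia <- istd(1L)
      emit(sample_id = sprintf("cal_%02d", i), run_id = "run1",
           replicate = 1L, role = "calibrator", level = sprintf("C%02d", i),
           transition_label = "analyte",
           analyte_area = ia * (config$slope * cal[i] + config$intercept) *
             lognormal_noise(1L, config$calibration_cv_pct),
           istd_area = ia, nominal_conc = cal[i])
    }
    for (r in seq_len(config$qc$runs)) {
      for (lv in names(config$qc$levels)) {
        conc <- config$qc$levels[[lv]]
        for (rep_i in seq_len(config$qc$replicates_per_run)) {
          ia <- istd(1L)
          emit(sample_id = sprintf("qc_%s_r%d_%d", lv, r, rep_i),
               run_id = sprintf("run%d", r), replicate = rep_i,
               role = "qc", level = lv, transition_label = "analyte",
               analyte_area = ia * (config$slope * conc +
                                      config$intercept) *
                 lognormal_noise(1L, config$qc_cv_pct[[lv]]),
               istd_area = ia, nominal_conc = conc)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate an N-terminal variant measurement set
#'
#' Variant intensities are proportional to their true shares times a common
#' response factor, with lognormal noise; variants whose normalized
#' intensity falls below `nd_threshold` report `NA` (not detected).
#'
#' @param config A [simulation_config()].
#' @return Data.frame with `variant`, `analyte_area`, `istd_area`, and
#'   `normalized` (`NA` when not detected).
#' @export
simulate_heterogeneity <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_sim_seed(config$seed, 2L, {
    shares <- config$heterogeneity_shares
    n <- length(shares)
    ia <- config$istd_mean * lognormal_noise(n, config$istd_cv_pct)
    resp <- shares * config$response_factor *
      lognormal_noise(n, config$heterogeneity_cv_pct)
    aa <- ia * resp
    normalized <- aa / ia
    normalized[normalized < config$nd_threshold] <- NA_real_
    aa[is.na(normalized)] <- NA_real_
    data.frame(variant = names(shares), analyte_area = aa, istd_area = ia,
               normalized = normalized, row.names = NULL,
               stringsAsFactors = FALSE)
  })
}

#' Simulate monomer/dimer oxidation-state measurements
#'
#' For each condition, monomer and dimer normalized intensities are drawn
#' from the condition's true fractions times a common response factor with
#' lognormal noise; species below `nd_threshold` report `NA` (not
#' detected).
#'
#' @param config A [simulation_config()].
#' @return Data.frame with `condition`, `monomer`, `dimer` normalized
#'   intensities, directly consumable by [oxidation_ratio()].
#' @export
simulate_oxidation <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_sim_seed(config$seed, 3L, {
    rows <- lapply(names(config$oxidation_fractions), function(cond) {
      fr <- config$oxidation_fractions[[cond]]
      val <- fr[c("monomer", "dimer")] * config$response_factor *
        lognormal_noise(2L, config$oxidation_cv_pct)
      val[val < config$nd_threshold] <- NA_real_
      data.frame(condition = cond, monomer = val[["monomer"]],
                 dimer = val[["dimer"]], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Run the full quantitation and validation pipeline on a measurement table
#'
#' Fits the calibration curve from the calibrator rows, back-calculates the
#' QC rows, assembles the precision/accuracy report, and applies the
#' guideline acceptance rules — the complete simulate/import-to-verdict
#' path.
#'
#' @param measurements Measurement data.frame as produced by
#'   [simulate_peak_areas()] or [read_peak_areas()].
#' @param design A [qc_design()]; QC rows are assigned to levels by their
#'   `nominal_conc`.
#' @param weighting Calibration weighting (see [fit_calibration()]).
#' @param thresholds A [guideline_thresholds()] list.
#' @return List with `curve`, `concentrations` (per-QC-sample
#'   back-calculations), `report`, `verdict`, and `selectivity` (`NULL`
#'   when the table has no blanks or no LLOQ QCs).
#' @export
quantify_study <- function(measurements, design = qc_design(),
                           weighting = "1/x^2",
                           thresholds = guideline_thresholds()) {
  curve <- fit_calibration(measurements, weighting)
  qc <- measurements[measurements$role == "qc", , drop = FALSE]
  if (!nrow(qc)) stop("no QC measurements", call. = FALSE)
  bc <- back_calculate(curve, qc)
  lv_idx <- vapply(qc$nominal_conc, function(x) {
    i <- which(abs(design$levels - x) <= 1e-6 * design$levels)
    if (length(i) != 1L) NA_integer_ else i
  }, integer(1L))
  if (any(is.na(lv_idx))) {
    stop("QC nominal_conc not matching any design level", call. = FALSE)
  }
  conc <- data.frame(run_id = qc$run_id,
                     level = names(design$levels)[lv_idx],
                     nominal = qc$nominal_conc, conc = bc$conc,
                     flag = bc$flag, stringsAsFactors = FALSE)
  report <- validation_report(conc, design)
  verdict <- guideline_check(report, curve, thresholds)
  blank <- measurements[measurements$role == "blank", , drop = FALSE]
  lloq_lab <- names(design$levels)[1L]
  lloq <- qc[conc$level == lloq_lab, , drop = FALSE]
  selectivity <- if (nrow(blank) && nrow(lloq)) {
    selectivity_check(blank, lloq, thresholds)
  }
  list(curve = curve, concentrations = conc, report = report,
       verdict = verdict, selectivity = selectivity)
}
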
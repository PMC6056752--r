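#' Internal-standard normalized response
#'
#' MRM peak areas are normalized to the co-injected internal standard (here
#' typically the synthetic peptide P14R) to cancel injection and ionization
#' variability.
#'
#' @param analyte_area Non-negative analyte peak areas.
#' @param istd_area Positive internal-standard peak areas.
#' @return `analyte_area / istd_area` (dimensionless).
#' @export
normalize_response <- function(analyte_area, istd_area) {
  if (any(!is.finite(istd_area)) || any(istd_area <= 0)) {
    stop("istd_area must be positive: failed injection?", call. = FALSE)
  }
  if (any(analyte_area < 0, na.rm = TRUE)) {
    stop("analyte_area must be non-negative", call. = FALSE)
  }
  analyte_area / istd_area
}

#' Concentrations of a serial-dilution calibration series
#'
#' @param top Highest calibrator concentration in ug/mL (default 100).
#' @param n Number of levels (default 10).
#' @param fold Dilution factor between levels (default 2).
#' @return Decreasing numeric vector of length `n`; the last element is the
#'   assay's lower limit of quantification (LLOQ).
#' @examples
#' calibration_levels()  # lowest level 100 / 2^9 = 0.195 ug/mL
#' @export
calibration_levels <- function(top = 100, n = 10L, fold = 2) {
  stopifnot(top > 0, n >= 1L, fold > 1)
  top / fold^(seq_len(n) - 1L)
}

#' Fit an ISTD-normalized calibration curve
#'
#' Weighted linear least squares of normalized response on nominal
#' concentration. The default `1/x^2` weighting is the standard choice for
#' bioanalytical LC-MS calibrations spanning about three orders of
#' magnitude: it equalizes the relative (rather than absolute) residuals, so
#' the low end of the curve is not swamped by the top calibrators.
#'
#' @param calibrators Data.frame of calibrator measurements with columns
#'   `analyte_area`, `istd_area`, `nominal_conc` (ug/mL); rows with a `role`
#'   column are filtered to `role == "calibrator"`.
#' @param weighting `"1/x^2"` (default), `"1/x"`, or `"none"`.
#' @param tolerance_pct,tolerance_lloq_pct Allowed back-calculated accuracy
#'   deviation per level, in percent (defaults 15 and 20; the wider bound
#'   applies to the lowest level).
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `weighting`, a per-level back-calculation table `levels` (nominal, n,
#'   mean back-calculated concentration, accuracy %, pass flag), and
#'   `usable_range`.
#' @export
fit_calibration <- function(calibrators, weighting = c("1/x^2", "1/x", "none"),
                            tolerance_pct = 15, tolerance_lloq_pct = 20) {
  weighting <- match.arg(weighting)
  if (!is.null(calibrators$role)) {
    calibrators <- calibrators[calibrators$role == "calibrator", ,
                               drop = FALSE]
  }
  x <- calibrators$nominal_conc
  if (any(is.na(x)) || any(x <= 0)) {
    stop("calibrators require positive nominal_conc", call. = FALSE)
  }
  lv <- sort(unique(x))
  if (length(lv) < 6L) {
    stop(sprintf("calibration requires >= 6 distinct levels, got %d",
                 length(lv)), call. = FALSE)
  }
  y <- normalize_response(calibrators$analyte_area, calibrators$istd_area)
  w <- switch(weighting, "1/x^2" = 1 / x^2, "1/x" = 1 / x, none = rep(1,
              length(x)))
  fit <- lm(y ~ x, weights = w)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration fit failed: non-positive slope", call. = FALSE)
  }
  back <- (y - intercept) / slope
  per_level <- do.call(rbind, lapply(lv, function(l) {
    b <- back[x == l]
    data.frame(nominal = l, n = length(b), mean_back = mean(b),
               accuracy_pct = 100 * mean(b) / l)
  }))
  tol <- ifelse(per_level$nominal == min(lv), tolerance_lloq_pct,
                tolerance_pct)
  per_level$pass <- abs(per_level$accuracy_pct - 100) <= tol
  structure(list(slope = slope, intercept = intercept,
                 weighting = weighting, fit = fit, levels = per_level,
                 usable_range = range(lv)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> response = %.6g * conc + %.6g  (weighting %s)\n",
              x$slope, x$intercept, x$weighting))
  cat(sprintf("usable range %.3g-%.3g ug/mL; %d/%d levels back-calculate in tolerance\n",
              x$usable_range[1L], x$usable_range[2L], sum(x$levels$pass),
              nrow(x$levels)))
  lev <- x$levels
  lev$mean_back <- signif_half_up(lev$mean_back)
  lev$accuracy_pct <- signif_half_up(lev$accuracy_pct)
  print.data.frame(lev, row.names = FALSE)
  invisible(x)
}

#' Back-calculate concentrations from a calibration curve
#'
#' Inverts the calibration line. Negative back-calculations are clamped to
#' zero and flagged rather than erroring, so validation tables can still be
#' aggregated; values outside the calibrated range are flagged.
#'
#' @param curve A [fit_calibration()] object.
#' @param measurements Data.frame with `analyte_area` and `istd_area`
#'   columns, or a numeric vector of normalized responses.
#' @return Data.frame with `response`, `conc` (ug/mL), and `flag`
#'   (`"ok"`, `"below_range"`, `"above_range"`).
#' @export
back_calculate <- function(curve, measurements) {
  stopifnot(inherits(curve, "calibration_curve"))
  y <- if (is.data.frame(measurements)) {
    normalize_response(measurements$analyte_area, measurements$istd_area)
  } else {
    as.numeric(measurements)
  }
  conc <- (y - curve$intercept) / curve$slope
  flag <- rep("ok", length(conc))
  flag[conc > curve$usable_range[2L]] <- "above_range"
  flag[conc < curve$usable_range[1L]] <- "below_range"
  neg <- conc < 0
  conc[neg] <- 0
  data.frame(response = y, conc = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' N-terminal heterogeneity content from a shared fragment ion
#'
#' N-terminal variants of a protein yield first tryptic peptides that differ
#' only in their N-terminal residues, so they share C-terminal y-series
#' fragments. Monitoring the common y ion of each variant precursor gives
#' comparable responses; this expresses each variant's ISTD-normalized
#' intensity as a percent of the most abundant variant (the conventional
#' reporting scale, most abundant = 100) and as its share of the variant
#' total.
#'
#' @param intensities Named numeric vector of ISTD-normalized intensities,
#'   one per variant. `NA` marks a not-detected variant and propagates.
#' @return Data.frame with `variant`, `intensity`, `percent_of_max`
#'   (most abundant variant = 100), and `share_pct` (percent of the summed
#'   variant intensities; detected shares sum to 100).
#' @examples
#' heterogeneity_content(c(main = 100, ala = 37.0, met_ala = 4.87))
#' @export
heterogeneity_content <- function(intensities) {
  if (length(intensities) < 2L) {
    stop("need at least two variants", call. = FALSE)
  }
  v <- names(intensities)
  if (is.null(v)) v <- paste0("variant", seq_along(intensities))
  det <- intensities[!is.na(intensities)]
  if (!length(det) || all(det == 0)) {
    stop("all variant intensities are zero or not detected", call. = FALSE)
  }
  data.frame(variant = v, intensity = as.numeric(intensities),
             percent_of_max = 100 * intensities / max(det),
             share_pct = 100 * intensities / sum(det),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Monomer/dimer oxidation ratio relative to reference conditions
#'
#' For a cysteine-containing peptide, oxidation forms a disulfide-bridged
#' homodimer. Monomer and dimer ISTD-normalized intensities are each
#' expressed as a percent of their own reference condition (the condition
#' assigned 100 in the experiment design, e.g. untreated control for the
#' monomer and fully oxidized for the dimer). Not-detected species (`NA`)
#' propagate as `NA` and print as `N.D.`, which is distinct from a measured
#' zero.
#'
#' @param data Data.frame with columns `condition`, `monomer`, `dimer`
#'   (ISTD-normalized intensities; `NA` = not detected).
#' @param monomer_reference,dimer_reference Condition labels that define
#'   100% for each species; `dimer_reference` may be `NA` if no condition
#'   anchors the dimer scale.
#' @return Data.frame of class `oxidation_ratio` with `condition`,
#'   `monomer_pct`, `dimer_pct`.
#' @export
oxidation_ratio <- function(data, monomer_reference,
                            dimer_reference = NA_character_) {
  stopifnot(all(c("condition", "monomer", "dimer") %in% names(data)))
  ref_row <- match(monomer_reference, data$condition)
  if (is.na(ref_row)) {
    stop(sprintf("monomer reference condition '%s' not present",
                 monomer_reference), call. = FALSE)
  }
  m_ref <- data$monomer[ref_row]
  if (is.na(m_ref) || m_ref <= 0) {
    stop("monomer reference intensity must be positive", call. = FALSE)
  }
  d_ref <- NA_real_
  if (!is.na(dimer_reference)) {
    dr <- match(dimer_reference, data$condition)
    if (is.na(dr)) {
      stop(sprintf("dimer reference condition '%s' not present",
                   dimer_reference), call. = FALSE)
    }
    d_ref <- data$dimer[dr]
  }
  out <- data.frame(condition = data$condition,
                    monomer_pct = 100 * data$monomer / m_ref,
                    dimer_pct = if (is.na(d_ref) || d_ref <= 0) NA_real_
                                else 100 * data$dimer / d_ref,
                    stringsAsFactors = FALSE)
  class(out) <- c("oxidation_ratio", "data.frame")
  out
}

#' @export
print.oxidation_ratio <- function(x, digits = 3L, ...) {
  fmt <- function(v) ifelse(is.na(v), "N.D.",
                            format(signif_half_up(v, digits)))
  show <- data.frame(condition = x$condition,
                     monomer_pct = fmt(x$monomer_pct),
                     dimer_pct = fmt(x$dimer_pct))
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}
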
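#' Monoisotopic residue masses for the 20 standard amino acids
#'
#' Residue (not free amino acid) monoisotopic masses in Da, named by
#' single-letter code. A peptide's neutral monoisotopic mass is the sum of
#' its residue masses plus one water.
#'
#' @format Named numeric vector of length 20.
#' @export
amino_acid_masses <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276, V =  99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Mass constants used throughout the package
#'
#' Monoisotopic masses (Da) of water and of a hydrogen atom, and the mass of
#' a proton. Protonation adds proton masses; homolytic bond bookkeeping
#' (e.g. disulfide formation, which loses two hydrogen atoms) uses the
#' hydrogen atom mass.
#'
#' @format Named list with elements `water`, `proton`, `hydrogen`.
#' @export
mass_constants <- list(
  water    = 18.010565,
  proton   =  1.007276,
  hydrogen =  1.007825
)

#' External mass-calibration reference peptides
#'
#' Sequences of synthetic peptides commonly used as singly protonated
#' external mass calibrants: the P14R peptide (fourteen prolines followed by
#' a C-terminal arginine, also the internal standard for MRM normalization),
#' bradykinin fragment 1-7, and angiotensin II.
#'
#' @format Named character vector.
#' @export
reference_peptides <- c(
  p14r           = "PPPPPPPPPPPPPPR",
  bradykinin_1_7 = "RPPGFSP",
  angiotensin_ii = "DRVYIHPF"
)

# Split a peptide into residues, erroring on anything outside the standard
# 20 codes; the error names the offending residue and its position.
split_residues <- function(peptide) {
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide) ||
      !nzchar(peptide)) {
    stop("peptide must be a single non-empty character string", call. = FALSE)
  }
  res <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  bad <- which(!(res %in% names(amino_acid_masses)))
  if (length(bad)) {
    stop(sprintf("non-standard residue '%s' at position %d of '%s'",
                 res[bad[1L]], bad[1L], peptide), call. = FALSE)
  }
  res
}

#' Monoisotopic mass of a peptide
#'
#' @param peptide Character vector of peptide sequences (standard single-letter
#'   codes, upper case).
#' @return Numeric vector of neutral monoisotopic masses in Da (residue masses
#'   plus one water).
#' @examples
#' monoisotopic_mass("VFCTK")
#' @export
monoisotopic_mass <- function(peptide) {
  vapply(peptide, function(p) {
    sum(amino_acid_masses[split_residues(p)]) + mass_constants$water
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Precursor m/z of a protonated peptide
#'
#' @inheritParams monoisotopic_mass
#' @param charge Positive integer charge state.
#' @return `(monoisotopic mass + charge * proton) / charge`, in Th.
#' @examples
#' precursor_mz("MHVAQPAVVLASSR", 3)
#' @export
precursor_mz <- function(peptide, charge) {
  charge <- as.integer(charge)
  if (any(is.na(charge)) || any(charge < 1L)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (monoisotopic_mass(peptide) + charge * mass_constants$proton) / charge
}

#' b/y fragment ion m/z
#'
#' Singly or multiply protonated monoisotopic m/z of a backbone fragment ion:
#' `b_i` is the sum of the first `i` residue masses plus the charge protons;
#' `y_i` is the sum of the last `i` residue masses plus water plus the charge
#' protons.
#'
#' @param peptide Single peptide sequence.
#' @param series `"b"` or `"y"`.
#' @param index Fragment index `i`, with `1 <= i < nchar(peptide)`.
#' @param charge Positive integer fragment charge (default 1).
#' @return Fragment m/z in Th.
#' @examples
#' fragment_mz("VFCTK", "y", 4)
#' @export
fragment_mz <- function(peptide, series = c("y", "b"), index, charge = 1L) {
  series <- match.arg(series)
  res <- split_residues(peptide)
  n <- length(res)
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L) || any(index >= n)) {
    stop(sprintf("fragment index must lie in [1, %d) for '%s'", n, peptide),
         call. = FALSE)
  }
  charge <- as.integer(charge)
  if (any(is.na(charge)) || any(charge < 1L)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  frag_mass <- vapply(index, function(i) {
    if (series == "b") sum(amino_acid_masses[res[seq_len(i)]])
    else sum(amino_acid_masses[res[seq.int(n - i + 1L, n)]]) +
      mass_constants$water
  }, numeric(1L))
  (frag_mass + charge * mass_constants$proton) / charge
}

#' Disulfide-linked peptide homodimer species
#'
#' For a peptide with exactly one cysteine, computes the oxidized
#' disulfide-bridged homodimer: dimer neutral mass (two monomers minus two
#' hydrogen atoms), its protonated precursor m/z, and the dehydro fragment
#' m/z observed after in-source disulfide cleavage (the normal fragment minus
#' one hydrogen atom).
#'
#' @param peptide Peptide sequence containing exactly one `C`.
#' @param precursor_charge Charge state for the dimer precursor (default 3).
#' @param fragment_series,fragment_index,fragment_charge Fragment to report in
#'   dehydro form; defaults to the singly charged y ion of length
#'   `nchar(peptide) - 1`.
#' @return List with `dimer_mass` (Da), `precursor_mz`, `fragment_label`, and
#'   `dehydro_fragment_mz`.
#' @examples
#' disulfide_dimer_species("VFCTK")
#' @export
disulfide_dimer_species <- function(peptide, precursor_charge = 3L,
                                    fragment_series = "y",
                                    fragment_index = NULL,
                                    fragment_charge = 1L) {
  res <- split_residues(peptide)
  n_cys <- sum(res == "C")
  if (n_cys != 1L) {
    stop(sprintf("'%s' has %d cysteines; the disulfide homodimer is defined for exactly one",
                 peptide, n_cys), call. = FALSE)
  }
  if (is.null(fragment_index)) fragment_index <- length(res) - 1L
  monomer <- monoisotopic_mass(peptide)
  dimer <- 2 * monomer - 2 * mass_constants$hydrogen
  list(
    dimer_mass = dimer,
    precursor_mz = (dimer + precursor_charge * mass_constants$proton) /
      precursor_charge,
    fragment_label = sprintf("%s%d", fragment_series, fragment_index),
    dehydro_fragment_mz = fragment_mz(peptide, fragment_series,
                                      fragment_index, fragment_charge) -
      mass_constants$hydrogen / fragment_charge
  )
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' reported m/z and validation cells), unlike [base::round()]'s banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @export
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Significant figures, half away from zero
#'
#' @param x Numeric vector.
#' @param digits Significant digits (default 3, the precision used in
#'   reported validation tables).
#' @export
signif_half_up <- function(x, digits = 3L) {
  out <- x
  nz <- is.finite(x) & x != 0
  d <- digits - 1L - floor(log10(abs(x[nz])))
  out[nz] <- round_half_up(x[nz], d)
  out
}
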
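#' Signature-peptide selection criteria
#'
#' The rule set used to screen tryptic peptides as surrogate (signature)
#' peptide candidates for protein quantitation by MRM: length between
#' `min_len` and `max_len` residues, no cysteine, no missed cleavage, not in
#' the vicinity of a disulfide bond, not the protein N- or C-terminal
#' peptide (terminal fragments carry amino-acid heterogeneity), and unique
#' against a background peptide set (the generalization of requiring
#' CDR-specific sequences for antibodies).
#'
#' @param min_len,max_len Allowed peptide length in residues (defaults 8
#'   and 15).
#' @param forbid_cys Disallow cysteine-containing peptides (default `TRUE`).
#' @param forbid_missed_cleavage Restrict candidates to fully cleaved
#'   peptides (default `TRUE`).
#' @param disulfide_window Residue distance below which a peptide counts as
#'   "in the vicinity" of an annotated disulfide cysteine (default 3; a
#'   convention of this package, exposed because no standard value exists).
#' @param forbid_terminal Disallow protein N-/C-terminal peptides
#'   (default `TRUE`).
#' @param require_unique Disallow peptides present in the background set
#'   (default `TRUE`).
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_len = 8L, max_len = 15L,
                               forbid_cys = TRUE,
                               forbid_missed_cleavage = TRUE,
                               disulfide_window = 3L,
                               forbid_terminal = TRUE,
                               require_unique = TRUE) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  disulfide_window <- as.integer(disulfide_window)
  if (min_len < 1L || min_len > max_len) {
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  }
  if (disulfide_window < 0L) stop("disulfide_window must be >= 0",
                                  call. = FALSE)
  structure(list(min_len = min_len, max_len = max_len,
                 forbid_cys = isTRUE(forbid_cys),
                 forbid_missed_cleavage = isTRUE(forbid_missed_cleavage),
                 disulfide_window = disulfide_window,
                 forbid_terminal = isTRUE(forbid_terminal),
                 require_unique = isTRUE(require_unique)),
            class = "selection_criteria")
}

# Collapse leucine/isoleucine to a common symbol: they are isobaric and MRM
# cannot tell them apart, so uniqueness must be judged on the collapsed
# alphabet.
collapse_il <- function(x) chartr("I", "L", x)

#' Background tryptic peptide set for uniqueness screening
#'
#' Union of all fully cleaved tryptic peptides of the supplied background
#' proteins, with isoleucine and leucine collapsed to a common symbol. A
#' candidate signature peptide present in this set cannot distinguish the
#' analyte from the background (e.g. endogenous IgG sharing the Fc
#' framework).
#'
#' @param proteins List of [therapeutic_protein()] objects or sequence
#'   strings (a single protein/string is accepted).
#' @param fc_only If `TRUE`, only the Fc-domain portion at/after each
#'   protein's `fusion_junction` contributes (the part shared with
#'   endogenous IgG).
#' @return Character vector of I/L-collapsed peptide sequences (a set).
#' @export
background_peptide_set <- function(proteins, fc_only = FALSE) {
  if (inherits(proteins, "therapeutic_protein") || is.character(proteins)) {
    proteins <- list(proteins)
  }
  if (!length(proteins)) {
    stop("at least one background protein is required", call. = FALSE)
  }
  peps <- unlist(lapply(proteins, function(p) {
    p <- as_protein(p)
    seqs <- if (fc_only) fc_region(p) else p$sequence
    digest(seqs, max_missed = 0L)$sequence
  }))
  sort(unique(collapse_il(peps)))
}

#' Screen and rank signature-peptide candidates
#'
#' Digests the protein, evaluates every peptide against the enabled
#' selection criteria, and returns all peptides (none are dropped) with
#' their violation labels, uniqueness flag, and rank. Peptides are ranked by
#' fewest violations, then longer peptides first, then N-to-C position.
#'
#' @param protein A [therapeutic_protein()].
#' @param criteria A [selection_criteria()] object.
#' @param background Character vector from [background_peptide_set()], or
#'   `NULL` to skip the uniqueness screen.
#' @param max_missed Missed cleavages enumerated when
#'   `forbid_missed_cleavage` is disabled (default 2).
#' @return A data.frame of class `candidate_report`: peptide columns from
#'   [digest()] plus `violations` (`;`-separated labels, `""` when the
#'   peptide passes), `n_violations`, `unique`, and `rank`.
#' @export
select_candidates <- function(protein, criteria = selection_criteria(),
                              background = NULL, max_missed = 2L) {
  protein <- as_protein(protein)
  stopifnot(inherits(criteria, "selection_criteria"))
  peps <- digest(protein,
                 max_missed = if (criteria$forbid_missed_cleavage) 0L
                              else max_missed)
  viol <- vector("list", nrow(peps))
  add <- function(v, cond, label) {
    v[cond] <- lapply(v[cond], c, label)
    v
  }
  viol <- add(viol, peps$length < criteria$min_len, "length_below_min")
  viol <- add(viol, peps$length > criteria$max_len, "length_above_max")
  if (criteria$forbid_cys) {
    viol <- add(viol, peps$contains_cys, "contains_cys")
  }
  if (criteria$forbid_missed_cleavage) {
    viol <- add(viol, peps$missed_cleavages > 0L, "missed_cleavage")
  }
  viol <- add(viol, peps$min_cys_distance < criteria$disulfide_window,
              "near_disulfide")
  if (criteria$forbid_terminal) {
    viol <- add(viol, peps$is_n_terminal, "n_terminal")
    viol <- add(viol, peps$is_c_terminal, "c_terminal")
  }
  if (is.null(background)) {
    peps$unique <- NA
  } else {
    peps$unique <- !(collapse_il(peps$sequence) %in% background)
    if (criteria$require_unique) {
      viol <- add(viol, !peps$unique, "not_unique")
    }
  }
  peps$violations <- vapply(viol, paste, character(1L), collapse = ";")
  peps$n_violations <- lengths(viol)
  ord <- order(peps$n_violations, -peps$length, peps$start)
  peps <- peps[ord, , drop = FALSE]
  peps$rank <- seq_len(nrow(peps))
  rownames(peps) <- NULL
  class(peps) <- c("candidate_report", "data.frame")
  peps
}

#' Violation labels of a candidate report row
#'
#' @param report A `candidate_report` from [select_candidates()].
#' @param peptide Peptide sequence to look up.
#' @return Character vector of violation labels (empty if the peptide
#'   passes all enabled criteria).
#' @export
candidate_violations <- function(report, peptide) {
  row <- report[report$sequence == peptide, , drop = FALSE]
  if (!nrow(row)) stop(sprintf("peptide '%s' not in report", peptide),
                       call. = FALSE)
  v <- strsplit(row$violations[1L], ";", fixed = TRUE)[[1L]]
  v[nzchar(v)]
}
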
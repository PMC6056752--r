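# Positions i such that trypsin cleaves between residues i and i+1:
# C-terminal to K or R, except when the next residue is proline.
cleavage_sites <- function(res) {
  n <- length(res)
  if (n < 2L) return(integer())
  i <- seq_len(n - 1L)
  i[res[i] %in% c("K", "R") & res[i + 1L] != "P"]
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein C-terminal to lysine and arginine (suppressed before
#' proline) and returns every peptide with up to `max_missed` internal
#' missed-cleavage sites, annotated with the properties the signature-peptide
#' selection rules use.
#'
#' @param protein A [therapeutic_protein()] or a bare sequence string.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @return A data.frame with one row per peptide: `sequence`, `start`, `end`
#'   (1-based inclusive coordinates in the parent), `length`,
#'   `missed_cleavages`, `is_n_terminal`, `is_c_terminal`, `contains_cys`,
#'   and `min_cys_distance` — the minimum residue distance from the peptide
#'   to the nearest annotated disulfide cysteine (0 if the peptide contains
#'   one, `Inf` if none is annotated).
#' @examples
#' digest("AAAKAAAR", max_missed = 1)
#' @export
digest <- function(protein, max_missed = 2L) {
  protein <- as_protein(protein)
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) {
    stop("max_missed must be a non-negative integer", call. = FALSE)
  }
  res <- split_residues(protein$sequence)
  n <- length(res)
  bounds <- c(0L, cleavage_sites(res), n)
  if (bounds[length(bounds)] != n) bounds <- c(bounds, n)
  bounds <- unique(bounds)
  nb <- length(bounds)
  rows <- list()
  for (j in seq_len(nb - 1L)) {
    for (k in seq.int(j + 1L, min(j + 1L + max_missed, nb))) {
      start <- bounds[j] + 1L
      end <- bounds[k]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = paste(res[start:end], collapse = ""),
        start = start, end = end, length = end - start + 1L,
        missed_cleavages = k - j - 1L,
        is_n_terminal = start == 1L,
        is_c_terminal = end == n,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$contains_cys <- grepl("C", out$sequence, fixed = TRUE)
  out$min_cys_distance <- min_cys_distance(out$start, out$end,
                                           protein$disulfide_cys_positions)
  out
}

# Minimum residue distance from the peptide [start, end] to the nearest
# annotated disulfide cysteine outside it; 0 if one lies inside, Inf if no
# cysteine is annotated. Distances are along the primary sequence.
min_cys_distance <- function(start, end, cys_positions) {
  if (!length(cys_positions)) return(rep(Inf, length(start)))
  mapply(function(s, e) {
    d <- ifelse(cys_positions < s, s - cys_positions,
                ifelse(cys_positions > e, cys_positions - e, 0L))
    min(d)
  }, start, end)
}

#' First tryptic peptides of N-terminal sequence variants
#'
#' Therapeutic proteins produced in engineered cell lines can circulate as a
#' mixture of N-terminal forms (e.g. with or without a retained initiator
#' methionine or a signal-peptide remnant). For each annotated variant
#' prefix, this constructs the variant sequence (prefix + parent sequence)
#' and returns its first tryptic peptide — the peptides whose common
#' C-terminal fragment ions are monitored to measure N-terminal
#' heterogeneity.
#'
#' @param protein A [therapeutic_protein()] with non-empty
#'   `alternative_starts`.
#' @return A data.frame with `variant` (label), `prefix`, `sequence` (the
#'   variant's first tryptic peptide), `start`, `end` (coordinates in the
#'   variant sequence), and `is_n_terminal` (always `TRUE`).
#' @examples
#' p <- therapeutic_protein("toy", "MHVAQPAVVLASSRGIAK",
#'                          alternative_starts = c(db = "", rr = "A",
#'                                                 kegg = "MA"))
#' enumerate_start_variants(p)
#' @export
enumerate_start_variants <- function(protein) {
  protein <- as_protein(protein)
  starts <- protein$alternative_starts
  if (is.null(starts) || !length(starts)) {
    stop("protein has no annotated alternative starts", call. = FALSE)
  }
  rows <- lapply(seq_along(starts), function(i) {
    variant_seq <- paste0(starts[[i]], protein$sequence)
    first <- digest(variant_seq, max_missed = 0L)[1L, ]
    data.frame(variant = names(starts)[i], prefix = starts[[i]],
               sequence = first$sequence, start = first$start,
               end = first$end, is_n_terminal = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
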
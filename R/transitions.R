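#' Build an MRM transition table for a peptide
#'
#' Enumerates precursor/fragment ion pairs for a peptide and assigns roles
#' the way an MRM method is typically set up: the highest-index fragment of
#' the first requested series is the quantitation transition and the next
#' `n_structure` fragments are structural-confirmation transitions
#' (configurable via `quant_index`).
#'
#' @param peptide Peptide sequence.
#' @param precursor_charge Integer vector of precursor charge states
#'   (default 2).
#' @param fragment_series Character vector drawn from `"y"`, `"b"`
#'   (default `"y"`).
#' @param fragment_charge Integer vector of fragment charge states
#'   (default 1).
#' @param n_structure Number of structural-confirmation transitions after
#'   the quantifier (default 2).
#' @param quant_index Fragment index of the quantifier; default the highest
#'   enumerated index of `fragment_series[1]`.
#' @param instrument_meta Optional one-row data.frame of opaque instrument
#'   settings (e.g. Q1/collision/Q3 voltages) replicated onto each row;
#'   carried through untouched, never computed.
#' @return A data.frame with columns `peptide`, `precursor_charge`,
#'   `precursor_mz`, `series`, `index`, `fragment_charge`, `fragment_mz`,
#'   `label` (e.g. `"y4+"`), and `role`
#'   (`"quantitation"`/`"structure"`/`"monitor"`).
#' @examples
#' build_transition_table("VFCTK", precursor_charge = 2)
#' @export
build_transition_table <- function(peptide,
                                   precursor_charge = 2L,
                                   fragment_series = "y",
                                   fragment_charge = 1L,
                                   n_structure = 2L,
                                   quant_index = NULL,
                                   instrument_meta = NULL) {
  res <- split_residues(peptide)
  n <- length(res)
  if (n < 2L) stop("peptide must have at least 2 residues", call. = FALSE)
  fragment_series <- match.arg(fragment_series, c("y", "b"),
                               several.ok = TRUE)
  grid <- expand.grid(precursor_charge = as.integer(precursor_charge),
                      series = fragment_series,
                      index = seq_len(n - 1L),
                      fragment_charge = as.integer(fragment_charge),
                      stringsAsFactors = FALSE)
  out <- data.frame(
    peptide = peptide,
    precursor_charge = grid$precursor_charge,
    precursor_mz = precursor_mz(peptide, 1L) * 0,  # filled below
    series = grid$series,
    index = grid$index,
    fragment_charge = grid$fragment_charge,
    stringsAsFactors = FALSE
  )
  out$precursor_mz <- vapply(out$precursor_charge,
                             function(z) precursor_mz(peptide, z),
                             numeric(1L))
  out$fragment_mz <- mapply(function(s, i, z) fragment_mz(peptide, s, i, z),
                            out$series, out$index, out$fragment_charge)
  out$label <- sprintf("%s%d%s", out$series, out$index,
                       strrep("+", out$fragment_charge))
  if (is.null(quant_index)) quant_index <- n - 1L
  prim <- out$series == fragment_series[1L] &
    out$fragment_charge == as.integer(fragment_charge)[1L] &
    out$precursor_charge == as.integer(precursor_charge)[1L]
  out$role <- "monitor"
  below <- prim & out$index <= quant_index
  ord <- order(-out$index)
  picked <- ord[below[ord]][seq_len(min(1L + n_structure, sum(below)))]
  out$role[picked] <- c("quantitation",
                        rep("structure", length(picked) - 1L))
  if (!is.null(instrument_meta)) {
    out <- cbind(out, instrument_meta[rep(1L, nrow(out)), , drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Match an observed transition to a computed transition table
#'
#' Finds the transition whose computed precursor (Q1) and fragment (Q3) m/z
#' are nearest to an observed pair, using the Chebyshev deviation
#' `max(|dQ1|, |dQ3|)`. Useful to reconcile instrument-optimized transition
#' lists (often printed at unit resolution) with exact monoisotopic values.
#'
#' @param q1,q3 Observed precursor and fragment m/z.
#' @param table Transition table from [build_transition_table()].
#' @param tolerance Maximum accepted deviation in Th (default 0.5).
#' @return The matching row of `table` with `delta_q1`, `delta_q3` and
#'   `deviation` columns appended, or `NULL` when nothing lies within
#'   tolerance. Ties are broken by smaller `|dQ1| + |dQ3|`, then by lower
#'   fragment index.
#' @examples
#' tab <- build_transition_table("VFCTK", precursor_charge = 2)
#' match_transition(299.3, 498.2, tab)
#' @export
match_transition <- function(q1, q3, table, tolerance = 0.5) {
  stopifnot(tolerance > 0)
  dq1 <- abs(table$precursor_mz - q1)
  dq3 <- abs(table$fragment_mz - q3)
  dev <- pmax(dq1, dq3)
  ok <- which(dev <= tolerance)
  if (!length(ok)) return(NULL)
  ord <- ok[order(dev[ok], dq1[ok] + dq3[ok], table$index[ok])]
  hit <- table[ord[1L], , drop = FALSE]
  hit$delta_q1 <- dq1[ord[1L]]
  hit$delta_q3 <- dq3[ord[1L]]
  hit$deviation <- dev[ord[1L]]
  rownames(hit) <- NULL
  hit
}

#' Write a transition table as CSV
#'
#' m/z values are rounded half-away-from-zero to one decimal, the precision
#' MRM method editors and printed transition lists use.
#'
#' @param table Transition table from [build_transition_table()].
#' @param path Output CSV path.
#' @param digits Decimal places for m/z columns (default 1).
#' @export
write_transition_table <- function(table, path, digits = 1L) {
  out <- table
  for (col in c("precursor_mz", "fragment_mz")) {
    out[[col]] <- round_half_up(out[[col]], digits)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
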
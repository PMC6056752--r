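#' Annotated therapeutic protein sequence
#'
#' Container for a therapeutic protein amino-acid sequence together with the
#' annotations the signature-peptide selection rules need: the residue
#' positions of disulfide-bonded cysteines, the first residue of the fused Fc
#' domain (for Fc-fusion constructs), and any reported N-terminal sequence
#' variants.
#'
#' @param id Short identifier (e.g. a FASTA record id).
#' @param sequence Amino-acid sequence, standard single-letter codes.
#'   Lower-case input is normalized to upper case.
#' @param name Free-text name; defaults to `id`.
#' @param disulfide_cys_positions Integer vector of 1-based residue indices
#'   annotated as disulfide-bonded cysteines; each must index a `C`.
#' @param fusion_junction Optional 1-based index of the first residue of the
#'   fused Fc domain.
#' @param alternative_starts Optional named character vector of N-terminal
#'   variant prefixes (name = variant label, value = prefix prepended to the
#'   parent sequence; `""` denotes the parent's own N-terminus).
#' @return An object of class `therapeutic_protein`.
#' @examples
#' therapeutic_protein("toy", "MHVAQPAVVLASSRGIAK",
#'                     alternative_starts = c(main = "", ala = "A"))
#' @export
therapeutic_protein <- function(id, sequence, name = id,
                                disulfide_cys_positions = integer(),
                                fusion_junction = NULL,
                                alternative_starts = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  res <- split_residues(sequence)
  n <- length(res)
  disulfide_cys_positions <- as.integer(disulfide_cys_positions)
  if (length(disulfide_cys_positions)) {
    if (any(disulfide_cys_positions < 1L | disulfide_cys_positions > n)) {
      stop("disulfide_cys_positions out of sequence bounds", call. = FALSE)
    }
    not_cys <- disulfide_cys_positions[res[disulfide_cys_positions] != "C"]
    if (length(not_cys)) {
      stop(sprintf("position %d annotated as disulfide cysteine but residue is '%s'",
                   not_cys[1L], res[not_cys[1L]]), call. = FALSE)
    }
  }
  if (!is.null(fusion_junction)) {
    fusion_junction <- as.integer(fusion_junction)
    if (is.na(fusion_junction) || fusion_junction < 1L || fusion_junction > n) {
      stop("fusion_junction out of sequence bounds", call. = FALSE)
    }
  }
  if (!is.null(alternative_starts)) {
    alternative_starts <- unlist(alternative_starts)
    storage.mode(alternative_starts) <- "character"
    if (is.null(names(alternative_starts)) ||
        any(!nzchar(names(alternative_starts)))) {
      stop("alternative_starts must be a named vector of prefixes",
           call. = FALSE)
    }
    for (p in alternative_starts[nzchar(alternative_starts)]) {
      split_residues(toupper(p))
    }
    prefixes <- toupper(unname(alternative_starts))
    alternative_starts <- setNames(prefixes, names(alternative_starts))
  }
  structure(
    list(id = id, name = name, sequence = sequence,
         disulfide_cys_positions = sort(disulfide_cys_positions),
         fusion_junction = fusion_junction,
         alternative_starts = alternative_starts),
    class = "therapeutic_protein"
  )
}

#' @export
print.therapeutic_protein <- function(x, ...) {
  cat(sprintf("<therapeutic_protein> %s (%s), %d aa\n",
              x$id, x$name, nchar(x$sequence)))
  cat(strwrap(x$sequence, width = 60), sep = "\n")
  if (length(x$disulfide_cys_positions)) {
    cat("disulfide Cys at:", paste(x$disulfide_cys_positions, collapse = ", "),
        "\n")
  }
  if (!is.null(x$fusion_junction)) {
    cat("Fc fusion junction at residue", x$fusion_junction, "\n")
  }
  if (!is.null(x$alternative_starts)) {
    cat("N-terminal variants:",
        paste(sprintf("%s='%s'", names(x$alternative_starts),
                      x$alternative_starts), collapse = ", "), "\n")
  }
  invisible(x)
}

# Coerce a bare sequence string to a minimal therapeutic_protein.
as_protein <- function(x) {
  if (inherits(x, "therapeutic_protein")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(therapeutic_protein("seq", x))
  }
  stop("expected a therapeutic_protein or a single sequence string",
       call. = FALSE)
}

#' Fc-domain portion of a fusion protein
#'
#' Returns the subsequence from the fusion junction onward (the
#' immunoglobulin Fc part shared with endogenous IgG); the whole sequence if
#' no junction is annotated.
#'
#' @param protein A [therapeutic_protein()].
#' @export
fc_region <- function(protein) {
  protein <- as_protein(protein)
  if (is.null(protein$fusion_junction)) return(protein$sequence)
  substring(protein$sequence, protein$fusion_junction, nchar(protein$sequence))
}
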
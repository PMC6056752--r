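#' Read therapeutic protein sequences from FASTA
#'
#' Reads amino-acid FASTA records (via Biostrings) and merges per-record
#' annotations — disulfide cysteine positions, fusion junction, N-terminal
#' variants — from a sidecar config keyed by FASTA record id. Lower-case
#' sequence is normalized to upper case; gap (`-`) and stop (`*`)
#' characters are rejected.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param annotations Optional annotations: a YAML file path or a named
#'   list. Each entry is keyed by record id and may hold `name`,
#'   `disulfide_cys_positions`, `fusion_junction`, and `alternative_starts`
#'   (a map of variant label to N-terminal prefix; use `""` for the parent
#'   form).
#' @return Named list of [therapeutic_protein()] objects, in file order.
#' @export
read_fasta <- function(path, annotations = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) {
                     stop(sprintf("malformed FASTA '%s': %s", path,
                                  conditionMessage(e)), call. = FALSE)
                   })
  if (!length(seqs)) stop(sprintf("no FASTA records in '%s'", path),
                          call. = FALSE)
  if (is.character(annotations)) {
    annotations <- yaml::read_yaml(annotations)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  proteins <- lapply(seq_along(seqs), function(i) {
    ann <- annotations[[ids[i]]]
    seq_chr <- toupper(as.character(seqs[[i]]))
    if (grepl("[-*]", seq_chr)) {
      stop(sprintf("record '%s' contains gap/stop characters", ids[i]),
           call. = FALSE)
    }
    alt <- ann$alternative_starts
    if (!is.null(alt)) {
      alt <- vapply(alt, function(p) if (is.null(p)) "" else as.character(p),
                    character(1L))
    }
    therapeutic_protein(
      id = ids[i], sequence = seq_chr,
      name = if (!is.null(ann$name)) ann$name else ids[i],
      disulfide_cys_positions =
        if (!is.null(ann$disulfide_cys_positions)) {
          ann$disulfide_cys_positions
        } else integer(),
      fusion_junction = ann$fusion_junction,
      alternative_starts = alt)
  })
  names(proteins) <- ids
  proteins
}

#' Write protein sequences to FASTA
#'
#' @param proteins List of [therapeutic_protein()] objects (or one).
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  if (inherits(proteins, "therapeutic_protein")) proteins <- list(proteins)
  set <- Biostrings::AAStringSet(vapply(proteins, `[[`, character(1L),
                                        "sequence"))
  names(set) <- vapply(proteins, `[[`, character(1L), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

peak_area_columns <- c("sample_id", "run_id", "replicate", "role",
                       "transition_label", "analyte_area", "istd_area",
                       "nominal_conc")

measurement_roles <- c("blank", "zero", "calibrator", "qc", "unknown")

#' Read an MRM peak-area table from CSV
#'
#' Expects a header with columns `sample_id`, `run_id`, `replicate`,
#' `role`, `transition_label`, `analyte_area`, `istd_area`, `nominal_conc`
#' (ug/mL; empty for blanks/zeros/unknowns) and optionally `level`. Roles
#' are validated against the vocabulary blank/zero/calibrator/qc/unknown;
#' areas must be non-negative (ISTD strictly positive); calibrator and QC
#' rows must carry a nominal concentration. Errors name the offending data
#' row.
#'
#' @param path CSV path.
#' @return Data.frame of typed measurements.
#' @export
read_peak_areas <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(peak_area_columns, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(df$level)) df$level[!nzchar(df$level)] <- NA_character_
  df$replicate <- as.integer(df$replicate)
  df$analyte_area <- as.numeric(df$analyte_area)
  df$istd_area <- as.numeric(df$istd_area)
  df$nominal_conc <- as.numeric(df$nominal_conc)
  bad_role <- which(!(df$role %in% measurement_roles))
  if (length(bad_role)) {
    stop(sprintf("row %d: unknown role '%s' (expected one of %s)",
                 bad_role[1L], df$role[bad_role[1L]],
                 paste(measurement_roles, collapse = "/")), call. = FALSE)
  }
  bad_area <- which(is.na(df$analyte_area) | df$analyte_area < 0 |
                      is.na(df$istd_area) | df$istd_area <= 0)
  if (length(bad_area)) {
    stop(sprintf("row %d: analyte_area must be >= 0 and istd_area > 0",
                 bad_area[1L]), call. = FALSE)
  }
  needs_nominal <- df$role %in% c("calibrator", "qc")
  bad_nom <- which(needs_nominal & (is.na(df$nominal_conc) |
                                      df$nominal_conc <= 0))
  if (length(bad_nom)) {
    stop(sprintf("row %d: %s sample lacks a positive nominal_conc",
                 bad_nom[1L], df$role[bad_nom[1L]]), call. = FALSE)
  }
  df
}

#' Write an MRM peak-area table to CSV
#'
#' Columns and units match [read_peak_areas()] (areas in arbitrary
#' intensity units, nominal concentrations in ug/mL), so write-then-read is
#' the identity.
#'
#' @param measurements Measurement data.frame.
#' @param path Output CSV path.
#' @export
write_peak_areas <- function(measurements, path) {
  missing <- setdiff(peak_area_columns, names(measurements))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  write.csv(measurements, path, row.names = FALSE, na = "")
  invisible(path)
}
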
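# Independent brute-force digestion oracle: enumerate every substring whose
# ends are valid trypsin cleavage boundaries (after K/R not before P) and
# whose internal boundary count is <= max_missed. Deliberately written
# without reusing any package internals.
brute_force_digest <- function(sequence, max_missed = 0L) {
  res <- strsplit(sequence, "")[[1L]]
  n <- length(res)
  boundaries <- 0L
  for (i in seq_len(n - 1L)) {
    if (res[i] %in% c("K", "R") && res[i + 1L] != "P") {
      boundaries <- c(boundaries, i)
    }
  }
  boundaries <- c(boundaries, n)
  out <- character()
  for (a in seq_along(boundaries)) {
    for (b in seq_along(boundaries)) {
      if (b > a && (b - a - 1L) <= max_missed) {
        out <- c(out, substr(sequence, boundaries[a] + 1L, boundaries[b]))
      }
    }
  }
  sort(out)
}

random_sequence <- function(len) {
  paste(sample(names(mrmsig::amino_acid_masses), len, replace = TRUE),
        collapse = "")
}

# Toy protein whose digest contains the cysteine signature peptide VFCTK as
# an internal peptide, plus one clean 10-mer candidate.
toy_cys_protein <- function() {
  therapeutic_protein(
    "toy_etn", "AAAKVFCTKVVVVTTTTTKAAAR",
    disulfide_cys_positions = 7L
  )
}

# Toy protein whose first tryptic peptide is the N-terminal signature
# peptide MHVAQPAVVLASSR, with the three reported N-terminal variants.
toy_nterm_protein <- function() {
  therapeutic_protein(
    "toy_abt", "MHVAQPAVVLASSRGIAK",
    alternative_starts = c(drugbank = "", review = "A", kegg = "MA")
  )
}

zero_violation_set <- function(report) {
  sort(report$sequence[report$n_violations == 0L])
}

extdata <- function(file) system.file("extdata", file, package = "mrmsig")
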
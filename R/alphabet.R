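#' Reduced yeast-like codon alphabet and codon-to-tRNA map
#'
#' The desk-scale fixtures use a reduced genetic code: 18 sense codons read by
#' 16 tRNA species covering 15 amino acids, plus one stop codon. Glutamine is
#' decoded by two isoacceptors (CAA by tRNA Gln-UUG, CAG by tRNA Gln-CUG) that
#' compete for the single glutaminyl-tRNA synthetase, mirroring the biology of
#' the Gln4 depletion system. Two amino acids (Ala, Gly) carry a pair of
#' synonymous codons decoded by one tRNA through wobble pairing at reduced
#' efficiency, so synonymous codons have different hopping rates.
#'
#' Every sense codon maps to exactly one tRNA species (many-to-one only);
#' wobble-decoded codons default to efficiency 0.64 relative to Watson-Crick
#' pairing, a configurable fixture convention.
#'
#' @return A tibble with columns `codon`, `amino_acid`, `species`, `anticodon`
#'   and `wobble` (efficiency factor in (0, 1]).
#' @seealso [generate_synthetic_transcriptome()], [synthetic_trna_table()]
#' @export
#' @examples
#' default_codon_map()
default_codon_map <- function() {
  tribble_map <- data.frame(
    codon = c("GCU", "GCC", "GGU", "GGC", "AAA", "AGA", "GAU", "GAA", "UUA",
              "UCU", "ACU", "GUU", "UUU", "CCA", "AAU", "AUU", "CAA", "CAG"),
    amino_acid = c("Ala", "Ala", "Gly", "Gly", "Lys", "Arg", "Asp", "Glu",
                   "Leu", "Ser", "Thr", "Val", "Phe", "Pro", "Asn", "Ile",
                   "Gln", "Gln"),
    anticodon = c("AGC", "AGC", "ACC", "ACC", "UUU", "UCU", "AUC", "UUC",
                  "UAA", "AGA", "AGU", "AAC", "AAA", "UGG", "AUU", "AAU",
                  "UUG", "CUG"),
    wobble = c(1, 0.64, 1, 0.64, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  tribble_map$species <- paste0(tribble_map$amino_acid, "-", tribble_map$anticodon)
  as_tibble(tribble_map[, c("codon", "amino_acid", "species", "anticodon", "wobble")])
}

#' @rdname default_codon_map
#' @export
stop_codon <- function() "UAA"

#' Glutamine codons of the alphabet
#'
#' @param codon_map a codon map tibble, see [default_codon_map()].
#' @return character vector of codons decoded by glutamine tRNAs.
#' @export
gln_codons <- function(codon_map = default_codon_map()) {
  codon_map$codon[codon_map$amino_acid == "Gln"]
}

validate_codon_map <- function(codon_map) {
  req <- c("codon", "species", "amino_acid", "wobble")
  missing <- setdiff(req, names(codon_map))
  if (length(missing) > 0) {
    abort(paste0("codon map lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(codon_map$codon)) {
    abort("codon map assigns some codon to more than one tRNA species")
  }
  if (any(codon_map$wobble <= 0 | codon_map$wobble > 1)) {
    abort("wobble efficiency factors must lie in (0, 1]")
  }
  sp <- unique(codon_map[, c("species", "amino_acid")])
  if (anyDuplicated(sp$species)) {
    abort("a tRNA species is assigned to more than one amino acid")
  }
  invisible(codon_map)
}
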
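DNA_BASES <- c("A", "C", "G", "T")
COMP_BASE <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Start codons recognized for bacterial CDS (translation table 11)
START_CODONS <- c("ATG", "GTG", "TTG")

AA_ONE_LETTER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

genetic_code_11 <- function() {
  if (is.null(.ea_env$gc11)) {
    .ea_env$gc11 <- Biostrings::getGeneticCode("11")
  }
  .ea_env$gc11
}

#' Translate codons with the bacterial genetic code
#'
#' Translates 3-nucleotide codons using NCBI translation table 11. Internal
#' codons are translated by the standard table (e.g. internal `GTG` is
#' valine); no initiator special-casing is applied. Stop codons return
#' `"*"`. Codons containing characters other than A/C/G/T (e.g. `N`) return
#' `NA_character_` ("untranslatable") rather than raising an error.
#'
#' @param codon Character vector of 3-letter codons (case-insensitive).
#' @return Character vector of one-letter amino-acid codes, `"*"` for stop,
#'   `NA` for untranslatable codons.
#' @examples
#' translate_codon(c("ATG", "TAA", "GTG", "ANA"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- unname(genetic_code_11()[codon])
  aa[!grepl("^[ACGT]{3}$", codon)] <- NA_character_
  aa
}

# vectorized reverse complement of character DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of single bases (vectorized)
comp_base <- function(b) unname(COMP_BASE[toupper(b)])

# mutate position `at` (1..3) of each codon to `alt` (all vectorized)
mutate_codon <- function(codon, at, alt) {
  paste0(substr(codon, 1, at - 1), alt, substr(codon, at + 1, 3))
}
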
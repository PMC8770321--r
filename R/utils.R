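#' Start codons considered by the TIS caller
#'
#' AUG plus its nine single-nucleotide neighbours (near-cognate start
#' codons), all decoded with initiator Met.
#'
#' @return Character vector of ten trinucleotides (DNA alphabet).
#' @export
startCodons <- function() {
  c("ATG", "CTG", "GTG", "TTG", "AAG", "ACG", "AGG", "ATA", "ATC", "ATT")
}

#' Small residues permitting initiator-Met excision
#'
#' Canonical Met-aminopeptidase specificity: the iMet is cleaved when the
#' second residue is small.
#'
#' @return Character vector of one-letter amino-acid codes.
#' @export
nmeSmallResidues <- function() {
  c("A", "C", "G", "P", "S", "T", "V")
}

#' N-terminal acetyltransferase substrate rule table
#'
#' Maps the mature N-terminus (after NME resolution) to the NAT class
#' expected to act on it co-translationally. Exposed (iMet-excised)
#' termini starting with a small residue are NatA substrates; retained-Met
#' termini are NatB (acidic/amide second residue) or NatC/E/F
#' (hydrophobic/basic second residue) substrates. Pro at either position
#' renders the terminus refractory to acetylation.
#'
#' @return Named list with components `natA`, `natB`, `natCEF`.
#' @export
natRuleTable <- function() {
  list(
    natA   = c("A", "S", "T", "V", "G", "C"),
    natB   = c("D", "E", "N", "Q"),
    natCEF = c("L", "I", "F", "W", "Y", "K", "H", "R", "M")
  )
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# reverse complement for plain character vectors of DNA
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# translate a DNA string (character) to protein, trimming a trailing
# partial codon; returns a character scalar of one-letter codes
translateDNA <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
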
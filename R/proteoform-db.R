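#' Translate a proteoform from a TIS in transcript coordinates
#'
#' Residue 1 is always Met regardless of the start codon (initiator tRNA
#' decoding of near-cognate codons); translation proceeds to the first
#' in-frame stop. When no stop occurs before the transcript end the
#' proteoform is emitted with a no-stop flag.
#'
#' @param txSeq Transcript sequence (character, 5' to 3').
#' @param tisPos 1-based transcript position of the codon's first
#'   nucleotide.
#' @return A list with \code{sequence} (one-letter amino acids, leading
#'   \code{M}), \code{codon} and \code{noStop}.
#' @export
translateFromTIS <- function(txSeq, tisPos) {
  if (is.na(tisPos) || tisPos < 1L || tisPos + 2L > nchar(txSeq))
    stop("TIS position outside transcript")
  codon <- substr(txSeq, tisPos, tisPos + 2L)
  aa <- translateDNA(substr(txSeq, tisPos, nchar(txSeq)))
  stop <- regexpr("*", aa, fixed = TRUE)
  noStop <- stop == -1L
  if (!noStop) aa <- substr(aa, 1L, stop - 1L)
  if (nchar(aa) == 0L) aa <- "M"
  substr(aa, 1L, 1L) <- "M"
  list(sequence = aa, codon = codon, noStop = noStop)
}

relationForCategory <- function(category, txPos, row) {
  switch(category,
         dbTIS = "annotated",
         cds_dTIS_inframe = "truncated_dTIS",
         cds_other_frame = "internal_ORF",
         leader3 = "leader_ORF",
         intergenic = "intergenic_ORF",
         leader5 = {
           if (!is.na(row$cdsStartTx) &&
               (row$cdsStartTx - txPos) %% 3L == 0L) "extended"
           else "leader_ORF"
         })
}

#' Build a proteoform search database from called TIS
#'
#' Annotated entries (one per coding transcript) come first; alternative
#' proteoforms translated from non-annotated called TIS are appended
#' with systematic accessions of the form
#' \code{GENE|TIS:<chrom>:<pos>:<codon>|<relation>}. Exact duplicate
#' sequences are collapsed with a cross-reference, and entries shorter
#' than \code{minLength} residues are dropped. For a 5'-leader TIS
#' in-frame with the annotated CDS and read through into it, the
#' relation is \code{extended}; an in-frame downstream TIS yields a
#' \code{truncated_dTIS} entry whose sequence is a suffix of its parent
#' (up to residue 1 when the start codon is near-cognate).
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param genome \code{DNAStringSet} keyed by chromosome.
#' @param calledTIS \code{data.frame} from \code{\link{callTIS}}.
#' @param minLength Minimum proteoform length in residues (default 7).
#' @return A list with \code{sequences} (named character vector,
#'   annotated entries first) and \code{mapping} (\code{data.frame}:
#'   \code{accession}, \code{gene}, \code{transcript}, \code{chrom},
#'   \code{pos}, \code{codon}, \code{relation}, \code{parentOffset},
#'   \code{noStop}, \code{duplicateOf}).
#' @export
buildProteoformDb <- function(models, genome, calledTIS, minLength = 7L) {
  info <- models@txInfo
  seqs <- transcriptSeqs(models, genome)
  entries <- list()
  # annotated proteome
  coding <- info[!is.na(info$cdsStartTx), , drop = FALSE]
  annSeq <- list()
  for (i in seq_len(nrow(coding))) {
    row <- coding[i, ]
    tr <- translateFromTIS(seqs[[row$transcript]], row$cdsStartTx)
    annSeq[[row$transcript]] <- tr$sequence
    entries[[length(entries) + 1L]] <- data.frame(
      accession = row$transcript, gene = row$gene,
      transcript = row$transcript, chrom = row$chrom,
      pos = txToGenome(models, row$transcript, row$cdsStartTx),
      codon = tr$codon, relation = "annotated", parentOffset = NA_integer_,
      noStop = tr$noStop, sequence = tr$sequence, stringsAsFactors = FALSE)
  }
  annStartPos <- vapply(entries, function(e) paste(e$chrom, e$pos),
                        character(1))
  # alternative proteoforms
  for (i in seq_len(nrow(calledTIS))) {
    tis <- calledTIS[i, ]
    if (paste(tis$chrom, tis$pos) %in% annStartPos) next
    if (!is.na(tis$transcript)) {
      if (!tis$transcript %in% info$transcript)
        stop("called TIS references unknown transcript ", tis$transcript)
      row <- txRow(models, tis$transcript)
      tr <- translateFromTIS(seqs[[tis$transcript]], tis$txPos)
      relation <- relationForCategory(tis$category, tis$txPos, row)
      parentOffset <- if (relation == "truncated_dTIS")
        (tis$txPos - row$cdsStartTx) %/% 3L else NA_integer_
      acc <- sprintf("%s|TIS:%s:%d:%s|%s", tis$gene, tis$chrom, tis$pos,
                     tis$codon, relation)
      entries[[length(entries) + 1L]] <- data.frame(
        accession = acc, gene = tis$gene, transcript = tis$transcript,
        chrom = tis$chrom, pos = tis$pos, codon = tr$codon,
        relation = relation, parentOffset = parentOffset, noStop = tr$noStop,
        sequence = tr$sequence, stringsAsFactors = FALSE)
    } else {
      # intergenic ORF: translate the genomic frame from the TIS
      chrSeq <- as.character(genome[[tis$chrom]])
      sub <- if (tis$strand == "+") substr(chrSeq, tis$pos, nchar(chrSeq))
             else revComp(substr(chrSeq, 1L, tis$pos))
      aa <- translateDNA(sub)
      stopAt <- regexpr("*", aa, fixed = TRUE)
      noStop <- stopAt == -1L
      if (!noStop) aa <- substr(aa, 1L, stopAt - 1L)
      if (nchar(aa) == 0L) next
      substr(aa, 1L, 1L) <- "M"
      acc <- sprintf("%s|TIS:%s:%d:%s|%s", "IGR", tis$chrom, tis$pos,
                     tis$codon, "intergenic_ORF")
      entries[[length(entries) + 1L]] <- data.frame(
        accession = acc, gene = NA_character_, transcript = NA_character_,
        chrom = tis$chrom, pos = tis$pos, codon = tis$codon,
        relation = "intergenic_ORF", parentOffset = NA_integer_,
        noStop = noStop, sequence = aa, stringsAsFactors = FALSE)
    }
  }
  mapping <- do.call(rbind, entries)
  mapping <- mapping[nchar(mapping$sequence) >= minLength |
                     mapping$relation == "annotated", , drop = FALSE]
  mapping <- mapping[!duplicated(mapping$accession), , drop = FALSE]
  # collapse exact duplicate sequences (keep first occurrence)
  mapping$duplicateOf <- NA_character_
  dup <- duplicated(mapping$sequence)
  if (any(dup)) {
    firstAcc <- mapping$accession[match(mapping$sequence, mapping$sequence)]
    mapping$duplicateOf[dup] <- firstAcc[dup]
  }
  kept <- mapping[!dup, , drop = FALSE]
  sequences <- kept$sequence
  names(sequences) <- kept$accession
  rownames(mapping) <- NULL
  list(sequences = sequences, mapping = mapping)
}

#' Write a proteoform database as FASTA plus mapping TSV
#'
#' @param db List from \code{\link{buildProteoformDb}}.
#' @param fastaPath,mappingPath Output files.
#' @return Invisibly, the FASTA path.
#' @export
writeProteoformDb <- function(db, fastaPath, mappingPath) {
  aa <- Biostrings::AAStringSet(db$sequences)
  Biostrings::writeXStringSet(aa, fastaPath)
  map <- db$mapping
  map$sequence <- NULL
  write.table(map, mappingPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}
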
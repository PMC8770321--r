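#' Write footprint alignments in the 4-column tabular dialect
#'
#' Columns: chromosome, 0-based genomic coordinate of the read 5' end,
#' strand, footprint length. No header.
#'
#' @param reads \code{data.frame} with \code{chrom}, \code{fivePrime}
#'   (1-based), \code{strand}, \code{length}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeAlignmentsTSV <- function(reads, path) {
  out <- data.frame(chrom = reads$chrom, fivePrime = reads$fivePrime - 1L,
                    strand = reads$strand, length = reads$length)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# genomic blocks covered by a read placed in transcript space; returns
# a data.frame(start, end) sorted by genomic coordinate, or NULL when
# the 5' end is not exonic
readBlocks <- function(models, chrom, strand, fivePrime, length) {
  info <- models@txInfo
  cand <- info[info$chrom == chrom & info$strand == strand, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    tx <- cand$transcript[i]
    fpTx <- genomeToTx(models, tx, fivePrime)
    if (is.na(fpTx)) next
    endTx <- min(fpTx + length - 1L, cand$txLen[i])
    g <- sort(txToGenome(models, tx, fpTx:endTx))
    brk <- c(0L, which(diff(g) != 1L), length(g))
    return(data.frame(start = g[head(brk, -1L) + 1L], end = g[brk[-1L]]))
  }
  NULL
}

#' Write footprint alignments as SAM
#'
#' Emits minimal single-end records (flag 16 for minus-strand reads,
#' M/N CIGARs for junction-spanning footprints when transcript models
#' are supplied, sequence and quality omitted).
#'
#' @param reads \code{data.frame} with \code{chrom}, \code{fivePrime}
#'   (1-based), \code{strand}, \code{length}.
#' @param genome \code{DNAStringSet} (for header sequence lengths).
#' @param path Output file.
#' @param models Optional \linkS4class{TranscriptModels} for spliced
#'   CIGARs.
#' @return Invisibly, the path.
#' @export
writeAlignmentsSAM <- function(reads, genome, path, models = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm,
                       length(genome[[nm]])), con)
  if (!nrow(reads)) return(invisible(path))
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    chrom <- reads$chrom[i]; strand <- reads$strand[i]
    fp <- reads$fivePrime[i]; len <- reads$length[i]
    blocks <- if (!is.null(models))
      readBlocks(models, chrom, strand, fp, len) else NULL
    if (is.null(blocks)) {
      pos <- if (strand == "+") fp else fp - len + 1L
      cigar <- sprintf("%dM", len)
    } else {
      pos <- blocks$start[1]
      m <- blocks$end - blocks$start + 1L
      cigar <- paste0(m[1], "M")
      for (j in seq_len(nrow(blocks) - 1L))
        cigar <- paste0(cigar, blocks$start[j + 1L] - blocks$end[j] - 1L,
                        "N", m[j + 1L], "M")
      clip <- len - sum(m)
      if (clip > 0L)
        cigar <- if (strand == "+") paste0(cigar, clip, "S")
                 else paste0(clip, "S", cigar)
    }
    flag <- if (strand == "+") 0L else 16L
    sprintf("r%06d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
            i, flag, chrom, pos, cigar)
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read an N-terminal PSM table
#'
#' Tab-separated with a header line; required columns \code{peptide},
#' \code{protein}, \code{start}, \code{modification}, \code{enzyme},
#' \code{q_value}; optional \code{intensity_light},
#' \code{intensity_heavy}.
#'
#' @param path File path.
#' @return \code{data.frame}.
#' @export
readPsmTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "protein", "start", "modification", "q_value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("PSM table misses columns: ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start)
  df
}

#' Write simulation outputs to a directory
#'
#' Writes genome FASTA, GFF3 annotation, LTM/CHX alignments (both the
#' tabular dialect and SAM), the PSM, TargetP-style and localization
#' tables, and the ground truth as JSON.
#'
#' @param config A \code{\link{simConfig}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the simulation objects and file
#'   paths.
#' @export
simulateAll <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateGenome(config)
  reads <- simulateFootprints(sim, config)
  psm <- simulatePsmTable(sim, config)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  writeAnnotationGFF3(sim$models, p("annotation.gff3"))
  for (tr in c("LTM", "CHX")) {
    sub <- reads[reads$treatment == tr, , drop = FALSE]
    writeAlignmentsTSV(sub, p(sprintf("%s.tsv", tolower(tr))))
    writeAlignmentsSAM(sub, sim$genome, p(sprintf("%s.sam", tolower(tr))),
                       models = sim$models)
  }
  write.table(psm$psms, p("psms.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(psm$targetp, p("targetp.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(psm$localization, p("localization.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(list(sim = sim, reads = reads, psm = psm, dir = dir,
                 paths = vapply(c("genome.fa", "annotation.gff3", "ltm.tsv",
                                  "chx.tsv", "ltm.sam", "chx.sam",
                                  "psms.tsv", "targetp.tsv",
                                  "localization.tsv", "truth.json"),
                                p, character(1))))
}
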
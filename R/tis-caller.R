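#' Category-specific TIS-calling thresholds
#'
#' Default thresholds follow the categorized calling strategy: annotated
#' starts (dbTIS) require 5 LTM counts and \eqn{R_{LTM}-R_{CHX} \ge
#' 0.01}; TIS in 5'/3' leaders or intergenic regions require 10 counts
#' and 0.05; TIS internal to a CDS require 15 counts and 0.15. Annotated
#' starts failing these rules are rescued when their CDS shows
#' elongating (CHX) ribosome occupancy of at least \code{rescueMinChx}
#' P-sites.
#'
#' @param dbTIS,leader5,leader3,intergenic,cds_internal Two-element
#'   numeric vectors \code{c(minCount, minRdiff)}.
#' @param rescueMinChx CHX P-sites within the CDS required to rescue a
#'   failing annotated start (default 10).
#' @param intergenicFlank Half-width (nt) of the pseudo-transcript used
#'   to normalize intergenic candidates (default 500).
#' @return A list of class \code{"tisThresholds"}.
#' @export
tisThresholds <- function(dbTIS = c(5, 0.01), leader5 = c(10, 0.05),
                          leader3 = c(10, 0.05), intergenic = c(10, 0.05),
                          cds_internal = c(15, 0.15), rescueMinChx = 10,
                          intergenicFlank = 500L) {
  th <- list(dbTIS = dbTIS, leader5 = leader5, leader3 = leader3,
             intergenic = intergenic, cds_internal = cds_internal,
             rescueMinChx = rescueMinChx,
             intergenicFlank = as.integer(intergenicFlank))
  for (cat in c("dbTIS", "leader5", "leader3", "intergenic", "cds_internal"))
    if (length(th[[cat]]) != 2L || any(th[[cat]] < 0))
      stop("threshold for ", cat, " must be c(minCount, minRdiff) >= 0")
  class(th) <- "tisThresholds"
  th
}

#' Transcript-normalized positional score
#'
#' \eqn{R_k = (X_k / N_k) \times 10}, where \eqn{X_k} is the footprint
#' count attributed to a position and \eqn{N_k} the total P-site count
#' on the transcript for treatment \eqn{k}.
#'
#' @param x Footprint count at the position.
#' @param n Total P-site count on the transcript (must be > 0; a
#'   transcript with zero reads in a treatment contributes R = 0, which
#'   the caller applies without calling this function).
#' @return Numeric score.
#' @examples
#' normalizedScore(5, 1000)  # 0.05
#' @export
normalizedScore <- function(x, n) {
  stopifnot(all(n > 0))
  (x / n) * 10
}

thresholdClass <- function(category) {
  switch(category,
         dbTIS = "dbTIS", leader5 = "leader5", leader3 = "leader3",
         intergenic = "intergenic",
         cds_dTIS_inframe = "cds_internal",
         cds_other_frame = "cds_internal",
         stop("unknown category ", category))
}

# positions (1-based) in a sequence where a start codon (AUG or
# near-cognate) begins
codonStartPositions <- function(seq) {
  L <- nchar(seq)
  if (L < 3L) return(integer())
  tri <- substring(seq, 1:(L - 2L), 3:L)
  which(tri %in% startCodons())
}

# Anchor a peak position to a start codon within +/-1 nt.
# Preference: zero offset, then an ATG anchor, then most 5'.
anchorPeak <- function(p, codonStarts, seq) {
  if (p %in% codonStarts) return(p)
  cand <- intersect(c(p - 1L, p + 1L), codonStarts)
  if (!length(cand)) return(NA_integer_)
  if (length(cand) == 1L) return(cand)
  codons <- substring(seq, cand, cand + 2L)
  isATG <- codons == "ATG"
  if (sum(isATG) == 1L) return(cand[isATG])
  min(cand)  # most 5' in transcript orientation
}

categorizeTxPos <- function(c, row, gpos, annotatedStarts) {
  key <- paste(row$chrom, row$strand, gpos)
  if (key %in% annotatedStarts) return("dbTIS")
  if (is.na(row$cdsStartTx)) return("leader5")
  if (c < row$cdsStartTx) return("leader5")
  if (c > row$cdsEndTx) return("leader3")
  if (c > row$cdsStartTx && (c - row$cdsStartTx) %% 3L == 0L)
    return("cds_dTIS_inframe")
  if (c == row$cdsStartTx) return("dbTIS")  # unreached: caught by key above
  "cds_other_frame"
}

windowSum <- function(v, c, half = 1L) {
  lo <- max(1L, c - half); hi <- min(length(v), c + half)
  sum(v[lo:hi])
}

# candidate TIS for one transcript; returns a data.frame (possibly empty)
transcriptCandidates <- function(txL, txC, seq, row, models, annotatedStarts) {
  L <- length(txL)
  empty <- data.frame(gene = character(), transcript = character(),
                      chrom = character(), strand = character(),
                      pos = integer(), txPos = integer(), codon = character(),
                      category = character(), ltmCount = numeric(),
                      rLtm = numeric(), rChx = numeric(), rdiff = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  peaks <- which(txL > 0L)
  if (!length(peaks)) return(empty)
  starts <- codonStartPositions(seq)
  keep <- vapply(peaks, function(p) {
    lo <- max(1L, p - 3L); hi <- min(L, p + 3L)
    txL[p] == max(txL[lo:hi])
  }, logical(1))
  peaks <- peaks[keep]
  if (!length(peaks)) return(empty)
  anchors <- vapply(peaks, anchorPeak, integer(1),
                    codonStarts = starts, seq = seq)
  ok <- !is.na(anchors)
  peaks <- peaks[ok]; anchors <- anchors[ok]
  if (!length(peaks)) return(empty)
  # one candidate per anchored codon
  o <- order(anchors, peaks)
  peaks <- peaks[o]; anchors <- anchors[o]
  first <- !duplicated(anchors)
  peaks <- peaks[first]; anchors <- anchors[first]
  # at most one candidate per 7-nt window: when two surviving peaks lie
  # within 3 nt (equal-count ties), prefer the ATG anchor, then most 5'
  if (length(peaks) > 1L) {
    codons <- substring(seq, anchors, anchors + 2L)
    keep <- rep(TRUE, length(peaks))
    for (i in seq_along(peaks)[-1L]) {
      prev <- which(keep[seq_len(i - 1L)])
      if (!length(prev)) next
      j <- max(prev)
      if (peaks[i] - peaks[j] <= 3L) {
        # tie within one window; peaks have equal counts or the max rule
        # would have removed one
        if (codons[i] == "ATG" && codons[j] != "ATG") {
          keep[j] <- FALSE
        } else {
          keep[i] <- FALSE
        }
      }
    }
    peaks <- peaks[keep]; anchors <- anchors[keep]
  }
  Nl <- sum(txL); Nc <- sum(txC)
  res <- lapply(seq_along(anchors), function(i) {
    c0 <- anchors[i]
    X <- windowSum(txL, c0)
    Xc <- windowSum(txC, c0)
    rL <- if (Nl > 0) normalizedScore(X, Nl) else 0
    rC <- if (Nc > 0) normalizedScore(Xc, Nc) else 0
    gpos <- txToGenome(models, row$transcript, c0)
    data.frame(gene = row$gene, transcript = row$transcript,
               chrom = row$chrom, strand = row$strand, pos = gpos,
               txPos = c0, codon = substr(seq, c0, c0 + 2L),
               category = categorizeTxPos(c0, row, gpos, annotatedStarts),
               ltmCount = X, rLtm = rL, rChx = rC, rdiff = rL - rC,
               status = "called", stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

intergenicCandidates <- function(ltm, chx, models, genome, flank) {
  pos <- ltm@positions
  if (!nrow(pos)) return(NULL)
  info <- models@txInfo
  exonic <- rep(FALSE, nrow(pos))
  for (i in seq_len(nrow(info))) {
    tx <- info$transcript[i]
    cand <- which(pos$chrom == info$chrom[i] & pos$strand == info$strand[i])
    if (!length(cand)) next
    hit <- !is.na(genomeToTx(models, tx, pos$pos[cand]))
    exonic[cand[hit]] <- TRUE
  }
  pos <- pos[!exonic, , drop = FALSE]
  if (!nrow(pos)) return(NULL)
  out <- list()
  cpos <- chx@positions
  for (i in seq_len(nrow(pos))) {
    chrom <- pos$chrom[i]; strand <- pos$strand[i]; p <- pos$pos[i]
    chrSeq <- as.character(genome[[chrom]])
    same <- ltm@positions[ltm@positions$chrom == chrom &
                          ltm@positions$strand == strand, , drop = FALSE]
    inwin <- same$count[abs(same$pos - p) <= 3L]
    if (pos$count[i] < max(inwin)) next
    # codon anchoring within +/-1 nt, in transcription direction
    cand <- c(p, p - 1L, p + 1L)
    codons <- vapply(cand, function(c0) {
      if (strand == "+") {
        if (c0 < 1L || c0 + 2L > nchar(chrSeq)) return(NA_character_)
        substr(chrSeq, c0, c0 + 2L)
      } else {
        if (c0 - 2L < 1L || c0 > nchar(chrSeq)) return(NA_character_)
        revComp(substr(chrSeq, c0 - 2L, c0))
      }
    }, character(1))
    ok <- which(!is.na(codons) & codons %in% startCodons())
    if (!length(ok)) next
    if (1L %in% ok) pick <- 1L
    else if (length(ok) == 1L) pick <- ok
    else {
      atg <- ok[codons[ok] == "ATG"]
      if (length(atg) == 1L) pick <- atg
      else pick <- ok[which.min(abs(cand[ok] - p) * 0 +
                                if (strand == "+") cand[ok] else -cand[ok])]
    }
    c0 <- cand[pick]
    csame <- cpos[cpos$chrom == chrom & cpos$strand == strand, , drop = FALSE]
    X <- sum(same$count[abs(same$pos - c0) <= 1L])
    Xc <- sum(csame$count[abs(csame$pos - c0) <= 1L])
    Nl <- sum(same$count[abs(same$pos - p) <= flank])
    Nc <- sum(csame$count[abs(csame$pos - p) <= flank])
    rL <- if (Nl > 0) normalizedScore(X, Nl) else 0
    rC <- if (Nc > 0) normalizedScore(Xc, Nc) else 0
    out[[length(out) + 1L]] <- data.frame(
      gene = NA_character_, transcript = NA_character_, chrom = chrom,
      strand = strand, pos = c0, txPos = NA_integer_, codon = codons[pick],
      category = "intergenic", ltmCount = X, rLtm = rL, rChx = rC,
      rdiff = rL - rC, status = "called", stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[!duplicated(res[c("chrom", "strand", "pos")]), , drop = FALSE]
}

#' Call translation initiation sites from LTM/CHX P-site tracks
#'
#' Implements categorized TIS calling: an LTM peak is a candidate when
#' it (i) carries the maximal LTM count within a 7-nt window, (ii) lies
#' within one nucleotide of the first position of an AUG or near-cognate
#' start codon (to which it is anchored), and passes category-specific
#' minimum-count and \eqn{R_{LTM}-R_{CHX}} thresholds. The count
#' attributed to a TIS is the LTM P-site count summed over the anchored
#' codon's first nucleotide plus/minus 1 nt, and \eqn{R} scores use the
#' transcript's total P-site count as \eqn{N_k} (an intergenic candidate
#' uses a pseudo-transcript of \code{intergenicFlank} nt either side of
#' the peak). Annotated starts failing the criteria are additionally
#' emitted with status \code{"rescued_dbTIS"} when their CDS carries at
#' least \code{rescueMinChx} CHX P-sites. Candidates at the same genomic
#' position supported by several transcripts of one gene are collapsed
#' to the record with maximal \eqn{R_{LTM}-R_{CHX}}.
#'
#' @param ltm,chx \linkS4class{PSiteTrack}s for the LTM and CHX
#'   treatments.
#' @param models A \linkS4class{TranscriptModels}.
#' @param genome \code{DNAStringSet} keyed by chromosome.
#' @param thresholds A \code{\link{tisThresholds}} object.
#' @return \code{data.frame} with columns \code{gene},
#'   \code{transcript}, \code{chrom}, \code{strand}, \code{pos} (1-based
#'   genomic coordinate of the codon's first nucleotide in transcription
#'   direction), \code{txPos}, \code{codon}, \code{category},
#'   \code{ltmCount}, \code{rLtm}, \code{rChx}, \code{rdiff},
#'   \code{status}.
#' @export
callTIS <- function(ltm, chx, models, genome, thresholds = tisThresholds()) {
  stopifnot(is(ltm, "PSiteTrack"), is(chx, "PSiteTrack"))
  info <- models@txInfo
  coding <- info[!is.na(info$cdsStartTx), , drop = FALSE]
  annotatedStarts <- vapply(seq_len(nrow(coding)), function(i) {
    paste(coding$chrom[i], coding$strand[i],
          txToGenome(models, coding$transcript[i], coding$cdsStartTx[i]))
  }, character(1))
  seqs <- transcriptSeqs(models, genome)
  rows <- list()
  for (i in seq_len(nrow(info))) {
    row <- info[i, ]
    txL <- txTrackCounts(ltm, models, row$transcript)
    txC <- txTrackCounts(chx, models, row$transcript)
    cand <- transcriptCandidates(txL, txC, seqs[[row$transcript]], row,
                                 models, annotatedStarts)
    if (nrow(cand)) {
      pass <- vapply(seq_len(nrow(cand)), function(j) {
        th <- thresholds[[thresholdClass(cand$category[j])]]
        cand$ltmCount[j] >= th[1] && cand$rdiff[j] >= th[2]
      }, logical(1))
      cand <- cand[pass, , drop = FALSE]
      if (nrow(cand)) rows[[length(rows) + 1L]] <- cand
    }
    # dbTIS rescue by elongating occupancy
    if (!is.na(row$cdsStartTx)) {
      startG <- txToGenome(models, row$transcript, row$cdsStartTx)
      called <- nrow(cand) > 0 && any(cand$pos == startG &
                                      cand$category == "dbTIS")
      if (!called) {
        cdsChx <- sum(txC[row$cdsStartTx:row$cdsEndTx])
        if (cdsChx >= thresholds$rescueMinChx) {
          c0 <- row$cdsStartTx
          X <- windowSum(txL, c0); Xc <- windowSum(txC, c0)
          Nl <- sum(txL); Nc <- sum(txC)
          rL <- if (Nl > 0) normalizedScore(X, Nl) else 0
          rC <- if (Nc > 0) normalizedScore(Xc, Nc) else 0
          rows[[length(rows) + 1L]] <- data.frame(
            gene = row$gene, transcript = row$transcript, chrom = row$chrom,
            strand = row$strand, pos = startG, txPos = c0,
            codon = substr(seqs[[row$transcript]], c0, c0 + 2L),
            category = "dbTIS", ltmCount = X, rLtm = rL, rChx = rC,
            rdiff = rL - rC, status = "rescued_dbTIS",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  inter <- intergenicCandidates(ltm, chx, models, genome,
                                thresholds$intergenicFlank)
  if (!is.null(inter)) {
    th <- thresholds$intergenic
    inter <- inter[inter$ltmCount >= th[1] & inter$rdiff >= th[2], ,
                   drop = FALSE]
    if (nrow(inter)) rows[[length(rows) + 1L]] <- inter
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), transcript = character(),
                      chrom = character(), strand = character(),
                      pos = integer(), txPos = integer(), codon = character(),
                      category = character(), ltmCount = numeric(),
                      rLtm = numeric(), rChx = numeric(), rdiff = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  # per-gene deduplication across transcripts: called beats rescued,
  # then maximal rdiff
  key <- paste(ifelse(is.na(res$gene), paste0("__ig_", res$chrom, res$strand),
                      res$gene), res$pos)
  o <- order(key, res$status != "called", -res$rdiff)
  res <- res[o, , drop = FALSE]
  res <- res[!duplicated(key[o]), , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a called-TIS table as TSV
#'
#' @param tis \code{data.frame} from \code{\link{callTIS}}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeTisTable <- function(tis, path) {
  write.table(tis, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
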
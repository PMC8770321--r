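#' Construct transcript models from components
#'
#' Low-level constructor used by the GFF3 reader and the simulator.
#'
#' @param txInfo Transcript table (see \linkS4class{TranscriptModels}).
#' @param exons Named list of exon data.frames (genomic 1-based
#'   inclusive coordinates, ordered 5' to 3' in transcript orientation).
#' @return A \linkS4class{TranscriptModels} object.
#' @export
transcriptModels <- function(txInfo, exons) {
  txInfo$transcript <- as.character(txInfo$transcript)
  txInfo$gene <- as.character(txInfo$gene)
  txInfo$chrom <- as.character(txInfo$chrom)
  txInfo$strand <- as.character(txInfo$strand)
  for (col in c("txLen", "cdsStartTx", "cdsEndTx"))
    txInfo[[col]] <- as.integer(txInfo[[col]])
  rownames(txInfo) <- NULL
  new("TranscriptModels", txInfo = txInfo, exons = exons[txInfo$transcript])
}

txRow <- function(models, transcript) {
  i <- match(transcript, models@txInfo$transcript)
  if (is.na(i)) stop("unknown transcript: ", transcript)
  models@txInfo[i, ]
}

#' Map transcript coordinates to genomic coordinates
#'
#' Walks the exon chain of one transcript. Coordinates are 1-based; the
#' genomic coordinate returned for a transcript position is the position
#' of that nucleotide on the chromosome (for minus-strand transcripts
#' coordinates decrease along the transcript).
#'
#' @param models A \linkS4class{TranscriptModels} object.
#' @param transcript Transcript identifier.
#' @param txpos Integer vector of transcript positions (1-based).
#' @return Integer vector of genomic positions (\code{NA} outside the
#'   transcript).
#' @export
txToGenome <- function(models, transcript, txpos) {
  ex <- models@exons[[transcript]]
  if (is.null(ex)) stop("unknown transcript: ", transcript)
  strand <- txRow(models, transcript)$strand
  w <- ex$end - ex$start + 1L
  ends <- cumsum(w)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- rep(NA_integer_, length(txpos))
  ok <- !is.na(txpos) & txpos >= 1L & txpos <= sum(w)
  if (any(ok)) {
    i <- findInterval(txpos[ok], starts)
    off <- txpos[ok] - starts[i]
    out[ok] <- if (strand == "+") ex$start[i] + off else ex$end[i] - off
  }
  out
}

#' Map genomic coordinates to transcript coordinates
#'
#' Inverse of \code{\link{txToGenome}}; genomic positions falling in an
#' intron or outside the transcript return \code{NA}.
#'
#' @inheritParams txToGenome
#' @param gpos Integer vector of genomic positions (1-based).
#' @return Integer vector of transcript positions.
#' @export
genomeToTx <- function(models, transcript, gpos) {
  ex <- models@exons[[transcript]]
  if (is.null(ex)) stop("unknown transcript: ", transcript)
  strand <- txRow(models, transcript)$strand
  w <- ex$end - ex$start + 1L
  ends <- cumsum(w)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(gpos) & gpos >= ex$start[i] & gpos <= ex$end[i]
    if (!any(hit)) next
    out[hit] <- if (strand == "+") starts[i] + (gpos[hit] - ex$start[i])
                else starts[i] + (ex$end[i] - gpos[hit])
  }
  out
}

#' Extract spliced transcript sequences
#'
#' @param models A \linkS4class{TranscriptModels} object.
#' @param genome A \code{DNAStringSet} keyed by chromosome.
#' @param transcripts Transcripts to extract (default all).
#' @return Named character vector of transcript sequences (5' to 3').
#' @export
transcriptSeqs <- function(models, genome, transcripts = NULL) {
  info <- models@txInfo
  if (is.null(transcripts)) transcripts <- info$transcript
  out <- vapply(transcripts, function(tx) {
    row <- txRow(models, tx)
    ex <- models@exons[[tx]]
    chr <- as.character(genome[[row$chrom]])
    # exons stored 5'->3' in tx orientation
    parts <- substring(chr, ex$start, ex$end)
    if (row$strand == "+") paste(parts, collapse = "")
    else paste(revComp(parts), collapse = "")
  }, character(1))
  names(out) <- transcripts
  out
}

#' Read transcript models from a GFF3 file
#'
#' Expects gene / mRNA / exon / CDS features with ID and Parent
#' attributes (the dialect written by \code{\link{writeAnnotationGFF3}}
#' and by standard genome annotation pipelines). The CDS interval is
#' projected into transcript coordinates through the exon chain.
#'
#' @param path GFF3 file path.
#' @return A \linkS4class{TranscriptModels} object.
#' @export
readTranscriptModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ == "mRNA"]
  if (!length(mrna)) stop("no mRNA features in ", path)
  info <- data.frame(
    transcript = as.character(mrna$ID),
    gene = as.character(unlist(mrna$Parent)),
    chrom = as.character(GenomicRanges::seqnames(mrna)),
    strand = as.character(GenomicRanges::strand(mrna)),
    txLen = NA_integer_, cdsStartTx = NA_integer_, cdsEndTx = NA_integer_,
    stringsAsFactors = FALSE)
  exing <- gr[typ == "exon"]
  cdsg <- gr[typ == "CDS"]
  exons <- list()
  for (i in seq_len(nrow(info))) {
    tx <- info$transcript[i]
    ex <- exing[vapply(exing$Parent, function(p) tx %in% p, logical(1))]
    ed <- data.frame(start = GenomicRanges::start(ex),
                     end = GenomicRanges::end(ex))
    ed <- ed[order(ed$start), , drop = FALSE]
    if (info$strand[i] == "-") ed <- ed[rev(seq_len(nrow(ed))), , drop = FALSE]
    rownames(ed) <- NULL
    exons[[tx]] <- ed
    info$txLen[i] <- sum(ed$end - ed$start + 1L)
    cd <- cdsg[vapply(cdsg$Parent, function(p) tx %in% p, logical(1))]
    if (length(cd)) {
      gstart <- min(GenomicRanges::start(cd))
      gend <- max(GenomicRanges::end(cd))
      m <- transcriptModels(info[i, , drop = FALSE], exons[tx])
      if (info$strand[i] == "+") {
        info$cdsStartTx[i] <- genomeToTx(m, tx, gstart)
        info$cdsEndTx[i] <- genomeToTx(m, tx, gend)
      } else {
        info$cdsStartTx[i] <- genomeToTx(m, tx, gend)
        info$cdsEndTx[i] <- genomeToTx(m, tx, gstart)
      }
    }
  }
  transcriptModels(info, exons)
}

#' Write transcript models as GFF3
#'
#' Emits gene, mRNA, exon, CDS (and UTR) features with 1-based inclusive
#' coordinates through \pkg{rtracklayer}.
#'
#' @param models A \linkS4class{TranscriptModels} object.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeAnnotationGFF3 <- function(models, path) {
  info <- models@txInfo
  rows <- list()
  for (i in seq_len(nrow(info))) {
    tx <- info$transcript[i]
    ex <- models@exons[[tx]]
    gstart <- min(ex$start); gend <- max(ex$end)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = info$chrom[i], start = gstart, end = gend, strand = info$strand[i],
      type = "gene", ID = info$gene[i], Parent = NA_character_,
      phase = NA_integer_)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = info$chrom[i], start = gstart, end = gend, strand = info$strand[i],
      type = "mRNA", ID = tx, Parent = info$gene[i],
      phase = NA_integer_)
    for (j in seq_len(nrow(ex)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = info$chrom[i], start = ex$start[j], end = ex$end[j],
        strand = info$strand[i], type = "exon",
        ID = sprintf("%s.exon%d", tx, j), Parent = tx,
        phase = NA_integer_)
    if (!is.na(info$cdsStartTx[i])) {
      # CDS genomic pieces: intersect exons with the CDS tx interval
      cdsTx <- seq(info$cdsStartTx[i], info$cdsEndTx[i])
      g <- txToGenome(models, tx, range(cdsTx))
      gr1 <- min(g); gr2 <- max(g)
      k <- 0L; cdsSoFar <- 0L
      for (j in seq_len(nrow(ex))) {
        s <- max(ex$start[j], gr1); e <- min(ex$end[j], gr2)
        if (s > e) next
        k <- k + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = info$chrom[i], start = s, end = e, strand = info$strand[i],
          type = "CDS", ID = sprintf("%s.cds%d", tx, k), Parent = tx,
          phase = (3L - cdsSoFar %% 3L) %% 3L)
        cdsSoFar <- cdsSoFar + (e - s + 1L)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start, df$end), strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
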
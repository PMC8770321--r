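#' P-site offset for a footprint length
#'
#' Ribosome footprints of 26--34 nt are assigned a P-site at a fixed
#' offset from their 5' end: +12 nt for lengths 26--30, +13 for 31--33
#' and +14 for 34. Other lengths are rejected.
#'
#' @param length Integer vector of footprint lengths (nt).
#' @return Integer vector of offsets; \code{NA} for rejected lengths.
#' @export
psiteOffset <- function(length) {
  out <- rep(NA_integer_, length(length))
  out[length >= 26L & length <= 30L] <- 12L
  out[length >= 31L & length <= 33L] <- 13L
  out[length == 34L] <- 14L
  out
}

#' Assign ribosome P-sites from footprint 5' ends
#'
#' The offset is applied in the direction of transcription: downstream
#' (increasing coordinates) on the plus strand and upstream (decreasing
#' coordinates) on the minus strand, where the 5' end is the rightmost
#' genomic coordinate of the read.
#'
#' @param fivePrime Integer vector, 1-based genomic coordinate of each
#'   read's 5' end.
#' @param strand Character vector of \code{"+"}/\code{"-"}.
#' @param length Integer vector of footprint lengths (nt).
#' @return Integer vector of 1-based P-site genomic coordinates;
#'   \code{NA} where the footprint length falls outside 26--34 nt.
#' @examples
#' assignPSite(101, "+", 26)  # 113 (offset +12)
#' assignPSite(101, "+", 34)  # 115 (offset +14)
#' assignPSite(101, "+", 25)  # NA, rejected
#' @export
assignPSite <- function(fivePrime, strand, length) {
  off <- psiteOffset(length)
  ifelse(strand == "+", fivePrime + off, fivePrime - off)
}

#' Read aligned ribosome footprints
#'
#' Accepts either the 4-column tabular dialect (\code{chrom},
#' \code{five_prime} as 0-based genomic coordinate of the read 5' end,
#' \code{strand}, \code{length}) or SAM/BAM, where the 5' end and the
#' footprint (query) length are derived from the alignment record
#' (flag 16 marks minus-strand reads whose 5' end is the rightmost
#' reference coordinate).
#'
#' @param path File path (.tsv/.txt, .sam or .bam).
#' @return A \code{data.frame} with columns \code{chrom},
#'   \code{fivePrime} (1-based), \code{strand}, \code{length}.
#' @export
readAlignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    bam <- if (ext == "sam") Rsamtools::asBam(path,
      destination = tempfile(), overwrite = TRUE, indexDestination = FALSE)
      else path
    ga <- GenomicAlignments::readGAlignments(bam)
    strand <- as.character(GenomicAlignments::strand(ga))
    fp <- ifelse(strand == "+", GenomicAlignments::start(ga),
                 GenomicAlignments::end(ga))
    data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
               fivePrime = as.integer(fp), strand = strand,
               length = GenomicAlignments::qwidth(ga),
               stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:4] <- c("chrom", "fivePrime", "strand", "length")
    df$fivePrime <- as.integer(df$fivePrime) + 1L  # dialect is 0-based
    df[c("chrom", "fivePrime", "strand", "length")]
  }
}

# Map read 5' ends through transcript models so that the P-site offset is
# applied in transcript space (junction-safe); reads whose 5' end is not
# exonic fall back to genomic-space offsetting.
psitesThroughModels <- function(reads, models) {
  info <- models@txInfo
  psite <- rep(NA_integer_, nrow(reads))
  off <- psiteOffset(reads$length)
  resolved <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(info))) {
    tx <- info$transcript[i]
    cand <- which(!resolved & !is.na(off) &
                  reads$chrom == info$chrom[i] &
                  reads$strand == info$strand[i])
    if (!length(cand)) next
    txpos <- genomeToTx(models, tx, reads$fivePrime[cand])
    hit <- !is.na(txpos)
    if (!any(hit)) next
    tgt <- txpos[hit] + off[cand[hit]]
    psite[cand[hit]] <- txToGenome(models, tx, tgt)
    resolved[cand[hit]] <- TRUE
  }
  left <- which(!resolved & !is.na(off))
  psite[left] <- assignPSite(reads$fivePrime[left], reads$strand[left],
                             reads$length[left])
  psite
}

#' Build a P-site count track from aligned footprints
#'
#' Each accepted read contributes one count at its assigned P-site;
#' multimapping alignment records each contribute one count. When
#' transcript models are supplied, offsets are applied in transcript
#' space so that footprints spanning exon-exon junctions resolve to the
#' correct spliced position; otherwise offsets are purely genomic.
#'
#' @param reads \code{data.frame} as returned by
#'   \code{\link{readAlignments}}.
#' @param treatment \code{"LTM"} or \code{"CHX"}.
#' @param models Optional \linkS4class{TranscriptModels} for
#'   junction-aware offsetting.
#' @param chromNames Optional character vector of valid chromosome
#'   names; reads on unknown chromosomes raise an error naming the
#'   offending record.
#' @return A \linkS4class{PSiteTrack}.
#' @export
buildTrack <- function(reads, treatment, models = NULL, chromNames = NULL) {
  stopifnot(treatment %in% c("LTM", "CHX"))
  if (!nrow(reads)) {
    return(new("PSiteTrack", treatment = treatment,
               positions = data.frame(chrom = character(), strand = character(),
                                      pos = integer(), count = integer()),
               nAccepted = 0L, nRejected = 0L))
  }
  if (!is.null(chromNames)) {
    bad <- which(!reads$chrom %in% chromNames)
    if (length(bad))
      stop("read ", bad[1], " maps to unknown chromosome '",
           reads$chrom[bad[1]], "'")
  }
  psite <- if (is.null(models)) {
    assignPSite(reads$fivePrime, reads$strand, reads$length)
  } else {
    psitesThroughModels(reads, models)
  }
  keep <- !is.na(psite)
  key <- paste(reads$chrom[keep], reads$strand[keep], psite[keep], sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  pos <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    strand = vapply(parts, `[`, "", 2L),
    pos = as.integer(vapply(parts, `[`, "", 3L)),
    count = as.integer(tab), stringsAsFactors = FALSE)
  pos <- pos[order(pos$chrom, pos$strand, pos$pos), ]
  rownames(pos) <- NULL
  new("PSiteTrack", treatment = treatment, positions = pos,
      nAccepted = sum(keep), nRejected = sum(!keep))
}

# per-transcript vector of P-site counts in transcript coordinates
txTrackCounts <- function(track, models, transcript) {
  row <- txRow(models, transcript)
  out <- integer(row$txLen)
  pos <- track@positions
  pos <- pos[pos$chrom == row$chrom & pos$strand == row$strand, , drop = FALSE]
  if (!nrow(pos)) return(out)
  txpos <- genomeToTx(models, transcript, pos$pos)
  hit <- !is.na(txpos)
  if (any(hit)) out[txpos[hit]] <- out[txpos[hit]] + pos$count[hit]
  out
}

#' Normalized metagene footprint density
#'
#' Per gene, P-site counts are divided by the mean count over the CDS
#' plus \code{flank} positions up- and downstream in the leaders; genes
#' with fewer than \code{minReads} mapped footprints in the treatment
#' (or a zero normalization denominator) are excluded and reported. The
#' aggregate profile is the mean of the per-gene normalized values at
#' positions aligned on the CDS start (relative position 0).
#'
#' @param track A \linkS4class{PSiteTrack}.
#' @param models A \linkS4class{TranscriptModels}; one (the first)
#'   transcript per gene is used as representative model.
#' @param flank Leader positions included either side of the CDS
#'   (default 20 nt).
#' @param minReads Minimum mapped footprints per gene (default 20).
#' @param codonBins If \code{TRUE}, counts are summed in 3-nt bins
#'   anchored on the reading frame before normalization.
#' @return A list with \code{perGene} (named list of data.frames with
#'   \code{relPos}, \code{norm}), \code{aggregate} (data.frame with
#'   \code{relPos}, \code{density}, \code{nGenes}) and \code{excluded}
#'   (named character vector of exclusion reasons).
#' @export
metageneDensity <- function(track, models, flank = 20L, minReads = 20L,
                            codonBins = FALSE) {
  info <- models@txInfo
  info <- info[!is.na(info$cdsStartTx), , drop = FALSE]
  info <- info[!duplicated(info$gene), , drop = FALSE]
  perGene <- list()
  excluded <- character()
  for (i in seq_len(nrow(info))) {
    tx <- info$transcript[i]
    cnt <- txTrackCounts(track, models, tx)
    if (sum(cnt) < minReads) {
      excluded[info$gene[i]] <- sprintf("fewer than %d mapped RPFs", minReads)
      next
    }
    w1 <- max(1L, info$cdsStartTx[i] - flank)
    w2 <- min(info$txLen[i], info$cdsEndTx[i] + flank)
    window <- w1:w2
    if (codonBins) {
      # 3-nt bins anchored on the CDS frame
      frame <- (window - info$cdsStartTx[i]) %% 3L
      bin <- window - frame
      cnt2 <- cnt
      agg <- tapply(cnt[window], bin, sum)
      cnt2[as.integer(names(agg))] <- as.numeric(agg)
      vals <- cnt2[window][frame == 0L]
      relPos <- (as.integer(names(agg)) - info$cdsStartTx[i])
    } else {
      vals <- cnt[window]
      relPos <- window - info$cdsStartTx[i]
    }
    denom <- mean(vals)
    if (denom == 0) {
      excluded[info$gene[i]] <- "zero normalization denominator"
      next
    }
    perGene[[info$gene[i]]] <- data.frame(relPos = relPos, norm = vals / denom)
  }
  if (length(perGene)) {
    all <- do.call(rbind, perGene)
    agg <- stats::aggregate(norm ~ relPos, data = all, FUN = mean)
    n <- stats::aggregate(norm ~ relPos, data = all, FUN = length)
    aggregate <- data.frame(relPos = agg$relPos, density = agg$norm,
                            nGenes = n$norm)
  } else {
    aggregate <- data.frame(relPos = integer(), density = numeric(),
                            nGenes = integer())
  }
  list(perGene = perGene, aggregate = aggregate, excluded = excluded)
}

#' Export a P-site track as bedGraph (one file per strand)
#'
#' @param track A \linkS4class{PSiteTrack}.
#' @param prefix Output path prefix; files
#'   \code{<prefix>.plus.bedgraph} and \code{<prefix>.minus.bedgraph}
#'   are written.
#' @return Invisibly, the two file paths.
#' @export
exportTrackBedGraph <- function(track, prefix) {
  paths <- character()
  for (s in c("+", "-")) {
    pos <- track@positions[track@positions$strand == s, , drop = FALSE]
    path <- paste0(prefix, if (s == "+") ".plus.bedgraph" else ".minus.bedgraph")
    if (nrow(pos)) {
      gr <- GenomicRanges::GRanges(pos$chrom,
        IRanges::IRanges(pos$pos, width = 1L), score = pos$count)
      rtracklayer::export(gr, path, format = "bedGraph")
    } else {
      writeLines(character(), path)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}
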
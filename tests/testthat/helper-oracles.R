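# Brute-force reimplementation of the TIS-calling criteria, written
# with naive loops and its own coordinate arithmetic so it can serve as
# an independent oracle for callTIS().

ORACLE_STARTS <- c("ATG", "CTG", "GTG", "TTG", "AAG", "ACG", "AGG",
                   "ATA", "ATC", "ATT")

oracleComplement <- function(x) chartr("ACGT", "TGCA", x)

# genomic position of every transcript position, by walking the exons
oracleTxMap <- function(exons, strand) {
  g <- integer(0)
  for (j in seq_len(nrow(exons))) {
    g <- if (strand == "+") c(g, exons$start[j]:exons$end[j])
         else c(g, exons$end[j]:exons$start[j])
  }
  g
}

oracleTxSeq <- function(map, strand, chrSeq) {
  out <- character(length(map))
  for (t in seq_along(map)) {
    base <- substr(chrSeq, map[t], map[t])
    out[t] <- if (strand == "+") base else oracleComplement(base)
  }
  paste(out, collapse = "")
}

oracleTxCounts <- function(trackDf, chrom, strand, map) {
  cnt <- integer(length(map))
  for (k in seq_len(nrow(trackDf))) {
    if (trackDf$chrom[k] != chrom || trackDf$strand[k] != strand) next
    t <- match(trackDf$pos[k], map)
    if (!is.na(t)) cnt[t] <- cnt[t] + trackDf$count[k]
  }
  cnt
}

oracleWindowSum <- function(cnt, c0) {
  s <- 0L
  for (q in (c0 - 1L):(c0 + 1L))
    if (q >= 1L && q <= length(cnt)) s <- s + cnt[q]
  s
}

# candidate peaks -> anchored codon starts, literal rule application
oracleAnchored <- function(cnt, seqStr) {
  L <- length(cnt)
  isStart <- logical(L)
  for (c0 in seq_len(max(0L, L - 2L)))
    if (substr(seqStr, c0, c0 + 2L) %in% ORACLE_STARTS) isStart[c0] <- TRUE
  peaks <- integer(0); anchors <- integer(0)
  for (p in seq_len(L)) {
    if (cnt[p] == 0L) next
    wmax <- 0L
    for (q in (p - 3L):(p + 3L))
      if (q >= 1L && q <= L && cnt[q] > wmax) wmax <- cnt[q]
    if (cnt[p] < wmax) next
    a <- NA_integer_
    if (isStart[p]) a <- p
    else {
      lo <- p - 1L; hi <- p + 1L
      loOk <- lo >= 1L && isStart[lo]
      hiOk <- hi + 2L <= L && isStart[hi]
      if (loOk && hiOk) {
        loATG <- substr(seqStr, lo, lo + 2L) == "ATG"
        hiATG <- substr(seqStr, hi, hi + 2L) == "ATG"
        a <- if (loATG && !hiATG) lo else if (hiATG && !loATG) hi else lo
      } else if (loOk) a <- lo else if (hiOk) a <- hi
    }
    if (is.na(a)) next
    peaks <- c(peaks, p); anchors <- c(anchors, a)
  }
  if (!length(peaks)) return(data.frame(peak = integer(), anchor = integer()))
  o <- order(anchors, peaks)
  peaks <- peaks[o]; anchors <- anchors[o]
  keepAnchor <- !duplicated(anchors)
  peaks <- peaks[keepAnchor]; anchors <- anchors[keepAnchor]
  keep <- rep(TRUE, length(peaks))
  if (length(peaks) > 1L) {
    for (i in 2:length(peaks)) {
      prev <- which(keep[1:(i - 1L)])
      if (!length(prev)) next
      j <- max(prev)
      if (peaks[i] - peaks[j] <= 3L) {
        iATG <- substr(seqStr, anchors[i], anchors[i] + 2L) == "ATG"
        jATG <- substr(seqStr, anchors[j], anchors[j] + 2L) == "ATG"
        if (iATG && !jATG) keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
  }
  data.frame(peak = peaks[keep], anchor = anchors[keep])
}

oracleCallTIS <- function(ltm, chx, models, genome, th = tisThresholds()) {
  info <- txInfo(models)
  exall <- txExons(models)
  ldf <- trackPositions(ltm); cdf <- trackPositions(chx)
  chrSeqs <- lapply(as.character(names(genome)),
                    function(n) as.character(genome[[n]]))
  names(chrSeqs) <- names(genome)
  maps <- list()
  annStart <- character(0)
  for (i in seq_len(nrow(info))) {
    maps[[info$transcript[i]]] <- oracleTxMap(exall[[info$transcript[i]]],
                                              info$strand[i])
    if (!is.na(info$cdsStartTx[i]))
      annStart <- c(annStart, paste(info$chrom[i], info$strand[i],
                                    maps[[info$transcript[i]]][info$cdsStartTx[i]]))
  }
  recs <- list()
  for (i in seq_len(nrow(info))) {
    row <- info[i, ]
    map <- maps[[row$transcript]]
    seqStr <- oracleTxSeq(map, row$strand, chrSeqs[[row$chrom]])
    cntL <- oracleTxCounts(ldf, row$chrom, row$strand, map)
    cntC <- oracleTxCounts(cdf, row$chrom, row$strand, map)
    Nl <- sum(cntL); Nc <- sum(cntC)
    anc <- oracleAnchored(cntL, seqStr)
    calledStart <- FALSE
    for (k in seq_len(nrow(anc))) {
      c0 <- anc$anchor[k]
      X <- oracleWindowSum(cntL, c0)
      Xc <- oracleWindowSum(cntC, c0)
      rL <- if (Nl > 0) X / Nl * 10 else 0
      rC <- if (Nc > 0) Xc / Nc * 10 else 0
      gpos <- map[c0]
      key <- paste(row$chrom, row$strand, gpos)
      category <-
        if (key %in% annStart) "dbTIS"
        else if (is.na(row$cdsStartTx) || c0 < row$cdsStartTx) "leader5"
        else if (c0 > row$cdsEndTx) "leader3"
        else if ((c0 - row$cdsStartTx) %% 3L == 0L) "cds_dTIS_inframe"
        else "cds_other_frame"
      thc <- switch(category, dbTIS = th$dbTIS, leader5 = th$leader5,
                    leader3 = th$leader3, th$cds_internal)
      if (X >= thc[1] && (rL - rC) >= thc[2]) {
        if (category == "dbTIS" && gpos == map[row$cdsStartTx])
          calledStart <- TRUE
        recs[[length(recs) + 1L]] <- data.frame(
          gene = row$gene, chrom = row$chrom, strand = row$strand,
          pos = gpos, codon = substr(seqStr, c0, c0 + 2L),
          category = category, ltmCount = X, rdiff = rL - rC,
          status = "called", stringsAsFactors = FALSE)
      }
    }
    if (!is.na(row$cdsStartTx) && !calledStart) {
      cdsChx <- 0L
      for (t in row$cdsStartTx:row$cdsEndTx) cdsChx <- cdsChx + cntC[t]
      if (cdsChx >= th$rescueMinChx) {
        c0 <- row$cdsStartTx
        X <- oracleWindowSum(cntL, c0); Xc <- oracleWindowSum(cntC, c0)
        rL <- if (Nl > 0) X / Nl * 10 else 0
        rC <- if (Nc > 0) Xc / Nc * 10 else 0
        recs[[length(recs) + 1L]] <- data.frame(
          gene = row$gene, chrom = row$chrom, strand = row$strand,
          pos = map[c0], codon = substr(seqStr, c0, c0 + 2L),
          category = "dbTIS", ltmCount = X, rdiff = rL - rC,
          status = "rescued_dbTIS", stringsAsFactors = FALSE)
      }
    }
  }
  # intergenic: LTM positions not exonic on their strand
  for (k in seq_len(nrow(ldf))) {
    chrom <- ldf$chrom[k]; strand <- ldf$strand[k]; p <- ldf$pos[k]
    exonic <- FALSE
    for (i in seq_len(nrow(info))) {
      if (info$chrom[i] != chrom || info$strand[i] != strand) next
      if (p %in% maps[[info$transcript[i]]]) { exonic <- TRUE; break }
    }
    if (exonic) next
    chrSeq <- chrSeqs[[chrom]]
    wmax <- 0L
    for (m in seq_len(nrow(ldf)))
      if (ldf$chrom[m] == chrom && ldf$strand[m] == strand &&
          abs(ldf$pos[m] - p) <= 3L && ldf$count[m] > wmax)
        wmax <- ldf$count[m]
    if (ldf$count[k] < wmax) next
    codonAt <- function(c0) {
      if (strand == "+") {
        if (c0 < 1L || c0 + 2L > nchar(chrSeq)) return(NA_character_)
        substr(chrSeq, c0, c0 + 2L)
      } else {
        if (c0 - 2L < 1L || c0 > nchar(chrSeq)) return(NA_character_)
        paste(rev(strsplit(oracleComplement(
          substr(chrSeq, c0 - 2L, c0)), "")[[1]]), collapse = "")
      }
    }
    cand <- c(p, p - 1L, p + 1L)
    codons <- vapply(cand, codonAt, character(1))
    ok <- which(!is.na(codons) & codons %in% ORACLE_STARTS)
    if (!length(ok)) next
    pick <- if (1L %in% ok) 1L
            else if (length(ok) == 1L) ok
            else {
              atg <- ok[codons[ok] == "ATG"]
              if (length(atg) == 1L) atg
              else if (strand == "+") ok[which.min(cand[ok])]
              else ok[which.max(cand[ok])]
            }
    c0 <- cand[pick]
    X <- 0L; Xc <- 0L; Nl <- 0L; Nc <- 0L
    for (m in seq_len(nrow(ldf))) {
      if (ldf$chrom[m] != chrom || ldf$strand[m] != strand) next
      if (abs(ldf$pos[m] - c0) <= 1L) X <- X + ldf$count[m]
      if (abs(ldf$pos[m] - p) <= th$intergenicFlank) Nl <- Nl + ldf$count[m]
    }
    for (m in seq_len(nrow(cdf))) {
      if (cdf$chrom[m] != chrom || cdf$strand[m] != strand) next
      if (abs(cdf$pos[m] - c0) <= 1L) Xc <- Xc + cdf$count[m]
      if (abs(cdf$pos[m] - p) <= th$intergenicFlank) Nc <- Nc + cdf$count[m]
    }
    rL <- if (Nl > 0) X / Nl * 10 else 0
    rC <- if (Nc > 0) Xc / Nc * 10 else 0
    if (X >= th$intergenic[1] && (rL - rC) >= th$intergenic[2])
      recs[[length(recs) + 1L]] <- data.frame(
        gene = NA_character_, chrom = chrom, strand = strand, pos = c0,
        codon = codons[pick], category = "intergenic", ltmCount = X,
        rdiff = rL - rC, status = "called", stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(gene = character(), chrom = character(),
                      strand = character(), pos = integer(),
                      codon = character(), category = character(),
                      ltmCount = numeric(), rdiff = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, recs)
  key <- paste(ifelse(is.na(res$gene), paste0("__ig_", res$chrom, res$strand),
                      res$gene), res$pos)
  o <- order(key, res$status != "called", -res$rdiff)
  res <- res[o, , drop = FALSE]
  res <- res[!duplicated(key[o]), , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# naive comparable projection of a callTIS result
tisComparable <- function(tis) {
  out <- tis[c("gene", "chrom", "strand", "pos", "codon", "category",
               "ltmCount", "rdiff", "status")]
  out <- out[order(out$chrom, out$pos, out$strand), ]
  out$rdiff <- round(out$rdiff, 10)
  rownames(out) <- NULL
  out
}
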
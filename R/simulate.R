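#' Simulation configuration with planted ground truth parameters
#'
#' Defines the conditions the synthetic data emulate: gene structure
#' ranges, the fraction of genes with in-frame downstream TIS (dTIS)
#' reached by leaky scanning, upstream ORFs, LTM peak sizes with
#' optional 1-nt jitter, CHX coverage with triplet periodicity and
#' 5'-to-3' decay, transit peptides with a planted
#' (V/I)-X-(A/C) | A cleavage motif and ragged aminopeptidase trimming,
#' and class-specific degrees of N-terminal acetylation.
#'
#' @param seed Integer seed; identical seed + config reproduce all
#'   outputs exactly.
#' @param nGenes Number of genes.
#' @param geneLengthRange CDS length range (nt; rounded to codons).
#' @param utr5LengthRange,utr3LengthRange Leader length ranges (nt).
#' @param intronGenesFraction Fraction of genes given one intron.
#' @param dtisFraction Fraction of genes with a planted in-frame dTIS.
#' @param leakyFraction Proportion of initiation events at the dTIS
#'   versus the annotated start.
#' @param uorfFraction Fraction of genes with a 5'-leader uORF.
#' @param ltmReadsPerTis Mean LTM footprints per TIS.
#' @param chxReadsPerGene Mean CHX footprints per gene.
#' @param chxDecay 5'-to-3' exponential decay constant (per nt).
#' @param periodicityWeight Fraction of CHX P-sites on frame-0
#'   positions.
#' @param readLengthWeights Named weights over footprint lengths
#'   26--34 nt.
#' @param enzymeSet Digestion enzymes emulated (trypsin cleaves after
#'   K/R, Glu-C after E/D; no missed cleavages).
#' @param ntaDegreeByClass Named planted degree (\%) per NAT class.
#' @param stromalNtaDegreeByResidue Named planted post-translational
#'   degree (\%) per stromal neo-terminus residue.
#' @param trimmingRange Range (residues) of aminopeptidase ragging
#'   downstream of the primary cleavage product.
#' @param intensityNoiseCV Coefficient of variation of precursor
#'   intensities.
#' @param noiseFraction Fraction of off-target footprint noise reads.
#' @param jitterProb Probability that an LTM P-site is displaced by
#'   1 nt.
#' @param ctpFraction,mtpFraction Fractions of genes given chloroplast
#'   / mitochondrial transit peptides.
#' @param decoyFraction Fraction of decoy PSM records (q > 0.01).
#' @param psmPerNterm PSMs emitted per N-terminus per enzyme.
#' @param nIntergenicOrfs Intergenic ORFs planted outside annotation.
#' @return A validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(seed = 1L, nGenes = 20L,
                      geneLengthRange = c(300L, 900L),
                      utr5LengthRange = c(60L, 120L),
                      utr3LengthRange = c(40L, 100L),
                      intronGenesFraction = 0.3, dtisFraction = 0.5,
                      leakyFraction = 0.3, uorfFraction = 0.2,
                      ltmReadsPerTis = 100, chxReadsPerGene = 200,
                      chxDecay = 0.002, periodicityWeight = 0.8,
                      readLengthWeights = c(`26` = 1, `27` = 2, `28` = 4,
                                            `29` = 6, `30` = 4, `31` = 2,
                                            `32` = 2, `33` = 1, `34` = 1),
                      enzymeSet = c("trypsin", "gluc"),
                      ntaDegreeByClass = c(NatA = 90, NatB = 95,
                                           NatCEF = 20, refractory = 0,
                                           none = 10),
                      stromalNtaDegreeByResidue = c(A = 34.9, S = 36.3,
                                                    V = 60.3, T = 50),
                      trimmingRange = c(1L, 3L), intensityNoiseCV = 0.1,
                      noiseFraction = 0.02, jitterProb = 0.1,
                      ctpFraction = 0.25, mtpFraction = 0.1,
                      decoyFraction = 0.1, psmPerNterm = 3L,
                      nIntergenicOrfs = 1L) {
  cfg <- as.list(environment())
  props <- c("intronGenesFraction", "dtisFraction", "leakyFraction",
             "uorfFraction", "periodicityWeight", "noiseFraction",
             "jitterProb", "ctpFraction", "mtpFraction", "decoyFraction")
  for (p in props)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must be a proportion in [0, 1]")
  if (cfg$nGenes < 1L) stop("nGenes must be at least 1")
  for (r in c("geneLengthRange", "utr5LengthRange", "utr3LengthRange"))
    if (length(cfg[[r]]) != 2L || any(cfg[[r]] < 20L) || diff(cfg[[r]]) < 0)
      stop(r, " must be an increasing range of at least 20 nt")
  lens <- as.integer(names(cfg$readLengthWeights))
  if (any(is.na(lens)) || any(lens < 26L) || any(lens > 34L))
    stop("read lengths are restricted to 26-34 nt")
  if (any(cfg$readLengthWeights < 0) || sum(cfg$readLengthWeights) <= 0)
    stop("readLengthWeights must be non-negative with positive sum")
  if (any(cfg$ntaDegreeByClass < 0 | cfg$ntaDegreeByClass > 100) ||
      any(cfg$stromalNtaDegreeByResidue < 0 |
          cfg$stromalNtaDegreeByResidue > 100))
    stop("planted NTA degrees must be percentages in [0, 100]")
  class(cfg) <- "simConfig"
  cfg
}

SENSE_CODONS <- local({
  nt <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# one fixed codon per residue, used when a specific amino acid must be
# planted at a protein position
CODON_FOR <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATC", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTC", W = "TGG", Y = "TAT")

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy genome with planted TIS, proteoforms and cleavages
#'
#' Builds genes in transcript space (5' leader, ATG-initiated CDS,
#' 3' leader), optionally inserts one GT..AG intron per selected gene,
#' then projects exon coordinates onto a single chromosome carrying the
#' genes on alternating strands separated by random intergenic spacers.
#' Planted features recorded in the ground truth: annotated starts
#' (always ATG), in-frame downstream TIS (ATG or one of the nine
#' near-cognate codons), 5'-leader uORFs, intergenic ORFs, transit
#' peptides with a (V/I)-X-(A/C) | A cleavage motif followed by planted
#' S/V/T trimming positions, and dual dTIS/cleavage sites where the
#' predicted P1' coincides with the iMet-excised dTIS N-terminus.
#'
#' @param config A \code{\link{simConfig}}.
#' @return A list with \code{genome} (\code{DNAStringSet}),
#'   \code{models} (\linkS4class{TranscriptModels}) and \code{truth}
#'   (list of data.frames: \code{tis}, \code{proteoforms},
#'   \code{cleavages}, \code{stromal}, \code{ntermini}).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  chrom <- "chr1"
  chrParts <- character()
  offset <- 0L
  info <- list(); exons <- list()
  tis <- list(); proteoforms <- list(); cleavages <- list()
  stromal <- list(); ntermini <- list()
  geneMeta <- list()
  for (gi in seq_len(config$nGenes)) {
    gene <- sprintf("G%03d", gi)
    txid <- paste0(gene, ".1")
    strand <- if (gi %% 2L == 1L) "+" else "-"
    nCod <- max(60L, round(sample(seq(config$geneLengthRange[1],
                                      config$geneLengthRange[2]), 1L) / 3L))
    utr5 <- sample(seq(config$utr5LengthRange[1],
                       config$utr5LengthRange[2]), 1L)
    utr3 <- sample(seq(config$utr3LengthRange[1],
                       config$utr3LengthRange[2]), 1L)
    codons <- c("ATG", sample(SENSE_CODONS, nCod - 2L, replace = TRUE), "TAA")
    # planted in-frame dTIS
    dtisIdx <- NA_integer_; dtisCodon <- NA_character_
    if (runif(1) < config$dtisFraction) {
      dtisIdx <- sample(seq(8L, min(40L, nCod - 15L)), 1L)
      dtisCodon <- if (runif(1) < 0.7) "ATG"
                   else sample(setdiff(startCodons(), "ATG"), 1L)
      codons[dtisIdx] <- dtisCodon
    }
    # transit peptide with planted cleavage motif
    ctp <- runif(1) < config$ctpFraction
    mtp <- !ctp && runif(1) < config$mtpFraction
    s1 <- NA_integer_; dual <- FALSE
    if (ctp || mtp) {
      if (!is.na(dtisIdx) && runif(1) < 0.5) {
        # dual case: predicted P1' coincides with the iMet-excised dTIS
        dual <- TRUE
        s1 <- dtisIdx
        codons[dtisIdx + 1L] <- CODON_FOR[["A"]]
      } else {
        repeat {
          s1 <- sample(seq(25L, min(45L, nCod - 15L)), 1L)
          if (is.na(dtisIdx) || abs(s1 - dtisIdx) >= 8L) break
        }
        codons[s1 - 2L] <- CODON_FOR[[sample(c("V", "I"), 1L)]]
        codons[s1] <- CODON_FOR[[sample(c("A", "C"), 1L)]]
        codons[s1 + 1L] <- CODON_FOR[["A"]]
        codons[s1 + 2L] <- CODON_FOR[["S"]]
        codons[s1 + 3L] <- CODON_FOR[["V"]]
        codons[s1 + 4L] <- CODON_FOR[["T"]]
      }
    }
    utr5Seq <- randomDNA(utr5)
    # planted uORF in the 5' leader
    uorfPos <- NA_integer_
    if (runif(1) < config$uorfFraction && utr5 >= 45L) {
      uorfPos <- sample(seq(20L, utr5 - 24L), 1L)
      uorf <- paste0("ATG", paste(sample(SENSE_CODONS, 4L, replace = TRUE),
                                  collapse = ""), "TAA")
      substr(utr5Seq, uorfPos, uorfPos + 17L) <- uorf
    }
    txSeq <- paste0(utr5Seq, paste(codons, collapse = ""), randomDNA(utr3))
    txLen <- nchar(txSeq)
    cdsStartTx <- utr5 + 1L
    cdsEndTx <- utr5 + 3L * nCod
    # optional intron inside the CDS
    hasIntron <- runif(1) < config$intronGenesFraction
    if (hasIntron) {
      ilen <- sample(60:120, 1L)
      ipos <- sample(seq(cdsStartTx + 10L, cdsEndTx - 10L), 1L)
      intron <- paste0("GT", randomDNA(ilen - 4L), "AG")
      body <- paste0(substr(txSeq, 1L, ipos), intron,
                     substr(txSeq, ipos + 1L, txLen))
      local_ex <- data.frame(ls = c(1L, ipos + ilen + 1L),
                             le = c(ipos, txLen + ilen))
    } else {
      body <- txSeq
      local_ex <- data.frame(ls = 1L, le = txLen)
    }
    B <- nchar(body)
    spacer <- randomDNA(sample(200:400, 1L))
    chrParts <- c(chrParts, spacer)
    offset <- offset + nchar(spacer)
    geneStart <- offset + 1L
    chrParts <- c(chrParts, if (strand == "+") body else revComp(body))
    offset <- offset + B
    ex <- if (strand == "+") {
      data.frame(start = geneStart + local_ex$ls - 1L,
                 end = geneStart + local_ex$le - 1L)
    } else {
      data.frame(start = geneStart + (B - local_ex$le),
                 end = geneStart + (B - local_ex$ls))
    }
    rownames(ex) <- NULL
    info[[txid]] <- data.frame(transcript = txid, gene = gene, chrom = chrom,
                               strand = strand, txLen = txLen,
                               cdsStartTx = cdsStartTx, cdsEndTx = cdsEndTx,
                               stringsAsFactors = FALSE)
    exons[[txid]] <- ex
    geneMeta[[gene]] <- list(tx = txid, dtisIdx = dtisIdx, s1 = s1,
                             dual = dual, ctp = ctp, mtp = mtp,
                             uorfPos = uorfPos, nCod = nCod, txSeq = txSeq,
                             cdsStartTx = cdsStartTx)
  }
  # intergenic ORFs (plus strand, not annotated)
  igOrfs <- list()
  for (k in seq_len(config$nIntergenicOrfs)) {
    spacer <- randomDNA(sample(200:300, 1L))
    chrParts <- c(chrParts, spacer)
    offset <- offset + nchar(spacer)
    orf <- paste0("ATG", paste(sample(SENSE_CODONS, 20L, replace = TRUE),
                               collapse = ""), "TAA")
    igOrfs[[k]] <- list(pos = offset + 1L, seq = orf)
    chrParts <- c(chrParts, orf)
    offset <- offset + nchar(orf)
  }
  chrParts <- c(chrParts, randomDNA(250L))
  genome <- Biostrings::DNAStringSet(paste(chrParts, collapse = ""))
  names(genome) <- chrom
  models <- transcriptModels(do.call(rbind, info), exons)
  # ground truth tables
  for (gene in names(geneMeta)) {
    gm <- geneMeta[[gene]]
    txid <- gm$tx
    row <- txRow(models, txid)
    prot <- translateFromTIS(gm$txSeq, gm$cdsStartTx)$sequence
    addTis <- function(category, txPos, codon, imet) {
      tis[[length(tis) + 1L]] <<- data.frame(
        gene = gene, transcript = txid, chrom = row$chrom,
        strand = row$strand, category = category, txPos = txPos,
        pos = txToGenome(models, txid, txPos), codon = codon, imet = imet,
        stringsAsFactors = FALSE)
    }
    addTis("dbTIS", gm$cdsStartTx, "ATG", 1L)
    proteoforms[[length(proteoforms) + 1L]] <- data.frame(
      gene = gene, protein = txid, relation = "annotated",
      sequence = prot, imet = 1L, stringsAsFactors = FALSE)
    # co-translational N-terminus of the annotated start
    addNterm <- function(protein, start, residues, class, degree, origin) {
      ntermini[[length(ntermini) + 1L]] <<- data.frame(
        protein = protein, start = start, residues = residues,
        natClass = class, degree = degree, origin = origin,
        stringsAsFactors = FALSE)
    }
    matureNterm <- function(imet) {
      second <- substr(prot, imet + 1L, imet + 1L)
      if (second %in% nmeSmallResidues())
        list(start = imet + 1L, residues = second)
      else list(start = imet, residues = paste0("M", second))
    }
    nt <- matureNterm(1L)
    cls <- natClass(nt$residues)
    addNterm(txid, nt$start, nt$residues, cls,
             unname(config$ntaDegreeByClass[cls]), "dbTIS")
    if (!is.na(gm$dtisIdx)) {
      dTxPos <- gm$cdsStartTx + 3L * (gm$dtisIdx - 1L)
      addTis("cds_dTIS_inframe", dTxPos,
             substr(gm$txSeq, dTxPos, dTxPos + 2L), gm$dtisIdx)
      dseq <- paste0("M", substr(prot, gm$dtisIdx + 1L, nchar(prot)))
      proteoforms[[length(proteoforms) + 1L]] <- data.frame(
        gene = gene, protein = txid, relation = "truncated_dTIS",
        sequence = dseq, imet = gm$dtisIdx, stringsAsFactors = FALSE)
      second <- substr(prot, gm$dtisIdx + 1L, gm$dtisIdx + 1L)
      nt <- if (second %in% nmeSmallResidues())
        list(start = gm$dtisIdx + 1L, residues = second)
        else list(start = gm$dtisIdx, residues = paste0("M", second))
      cls <- natClass(nt$residues)
      isDual <- !is.na(gm$s1) && abs(nt$start - (gm$s1 + 1L)) <= 5L
      addNterm(txid, nt$start, nt$residues, cls,
               unname(config$ntaDegreeByClass[cls]),
               if (isDual) "dual_dTIS_cTP" else "dTIS")
    }
    if (!is.na(gm$uorfPos))
      addTis("leader5", gm$uorfPos, "ATG", NA_integer_)
    if (!is.na(gm$s1)) {
      cleavages[[length(cleavages) + 1L]] <- data.frame(
        protein = txid, prediction = if (gm$ctp) "cTP" else "mTP",
        site = gm$s1, stringsAsFactors = FALSE)
      dtisStarts <- if (is.na(gm$dtisIdx)) integer(0)
                    else c(gm$dtisIdx, gm$dtisIdx + 1L)
      trims <- seq(config$trimmingRange[1], config$trimmingRange[2])
      starts <- c(gm$s1 + 1L, gm$s1 + 1L + trims[runif(length(trims)) < 0.7])
      for (st in starts) {
        if (st %in% dtisStarts) next  # merged with the dTIS N-terminus
        res <- substr(prot, st, st)
        deg <- config$stromalNtaDegreeByResidue[res]
        if (is.na(deg)) deg <- 30
        stromal[[length(stromal) + 1L]] <- data.frame(
          protein = txid, start = st, residue = res, degree = unname(deg),
          stringsAsFactors = FALSE)
        addNterm(txid, st, res, NA_character_, unname(deg),
                 if (gm$ctp) "cTP_neo" else "mTP_neo")
      }
    }
  }
  for (k in seq_along(igOrfs))
    tis[[length(tis) + 1L]] <- data.frame(
      gene = NA_character_, transcript = NA_character_, chrom = chrom,
      strand = "+", category = "intergenic", txPos = NA_integer_,
      pos = igOrfs[[k]]$pos, codon = "ATG", imet = NA_integer_,
      stringsAsFactors = FALSE)
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  truth <- list(
    tis = bind(tis, data.frame()),
    proteoforms = bind(proteoforms, data.frame()),
    cleavages = bind(cleavages, data.frame(protein = character(),
      prediction = character(), site = integer())),
    stromal = bind(stromal, data.frame(protein = character(),
      start = integer(), residue = character(), degree = numeric())),
    ntermini = bind(ntermini, data.frame()))
  list(genome = genome, models = models, truth = truth)
}

sampleReadLength <- function(n, weights) {
  lens <- as.integer(names(weights))
  sample(lens, n, replace = TRUE, prob = weights)
}

#' Simulate LTM and CHX footprint alignments
#'
#' LTM 5' ends are placed so that the length-dependent P-site offset
#' lands on planted TIS first nucleotides (with 1-nt jitter at
#' \code{jitterProb}); initiation events split between the annotated
#' start and the planted dTIS according to \code{leakyFraction}. CHX
#' P-sites span the CDS with frame-0 enrichment
#' (\code{periodicityWeight}) and 5'-to-3' exponential decay
#' (\code{chxDecay}). A \code{noiseFraction} of off-target reads is
#' placed uniformly on the genome.
#'
#' @param sim Output of \code{\link{simulateGenome}}.
#' @param config The same \code{\link{simConfig}}.
#' @return \code{data.frame} with columns \code{chrom},
#'   \code{fivePrime} (1-based genomic), \code{strand}, \code{length},
#'   \code{treatment}.
#' @export
simulateFootprints <- function(sim, config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed + 1L)
  models <- sim$models
  truth <- sim$truth
  reads <- list()
  emitTx <- function(txid, txPsites, treatment) {
    if (!length(txPsites)) return()
    row <- txRow(models, txid)
    lens <- sampleReadLength(length(txPsites), config$readLengthWeights)
    fpTx <- txPsites - psiteOffset(lens)
    ok <- fpTx >= 1L
    g <- txToGenome(models, txid, fpTx[ok])
    reads[[length(reads) + 1L]] <<- data.frame(
      chrom = row$chrom, fivePrime = g, strand = row$strand,
      length = lens[ok], treatment = treatment, stringsAsFactors = FALSE)
  }
  jitter <- function(n) {
    j <- integer(n)
    hit <- runif(n) < config$jitterProb
    j[hit] <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
    j
  }
  info <- models@txInfo
  for (i in seq_len(nrow(info))) {
    txid <- info$transcript[i]
    gtis <- truth$tis[!is.na(truth$tis$transcript) &
                      truth$tis$transcript == txid, , drop = FALSE]
    db <- gtis[gtis$category == "dbTIS", , drop = FALSE]
    dt <- gtis[gtis$category == "cds_dTIS_inframe", , drop = FALSE]
    uo <- gtis[gtis$category == "leader5", , drop = FALSE]
    nInit <- rpois(1L, config$ltmReadsPerTis)
    if (nrow(dt)) {
      nDt <- rbinom(1L, nInit, config$leakyFraction)
      emitTx(txid, rep(dt$txPos[1], nDt) + jitter(nDt), "LTM")
      nDb <- nInit - nDt
    } else nDb <- nInit
    if (nrow(db)) emitTx(txid, rep(db$txPos[1], nDb) + jitter(nDb), "LTM")
    if (nrow(uo)) {
      nU <- rpois(1L, config$ltmReadsPerTis)
      emitTx(txid, rep(uo$txPos[1], nU) + jitter(nU), "LTM")
    }
    # CHX: codon positions with decay and triplet periodicity
    nC <- rpois(1L, config$chxReadsPerGene)
    if (nC > 0L) {
      nCod <- (info$cdsEndTx[i] - info$cdsStartTx[i] + 1L) %/% 3L
      w <- exp(-config$chxDecay * 3 * seq_len(nCod))
      cod <- sample(seq_len(nCod), nC, replace = TRUE, prob = w)
      frame <- ifelse(runif(nC) < config$periodicityWeight, 0L,
                      sample(1:2, nC, replace = TRUE))
      emitTx(txid, info$cdsStartTx[i] + 3L * (cod - 1L) + frame, "CHX")
    }
  }
  # intergenic ORFs: plus strand, genomic-space placement
  ig <- truth$tis[truth$tis$category == "intergenic", , drop = FALSE]
  for (k in seq_len(nrow(ig))) {
    n <- rpois(1L, config$ltmReadsPerTis)
    if (!n) next
    lens <- sampleReadLength(n, config$readLengthWeights)
    fp <- ig$pos[k] + jitter(n) - psiteOffset(lens)
    reads[[length(reads) + 1L]] <- data.frame(
      chrom = ig$chrom[k], fivePrime = fp, strand = "+", length = lens,
      treatment = "LTM", stringsAsFactors = FALSE)
  }
  out <- if (length(reads)) do.call(rbind, reads) else
    data.frame(chrom = character(), fivePrime = integer(),
               strand = character(), length = integer(),
               treatment = character(), stringsAsFactors = FALSE)
  # off-target noise
  if (config$noiseFraction > 0 && nrow(out)) {
    chrLen <- nchar(as.character(sim$genome[[1]]))
    nN <- round(config$noiseFraction * nrow(out))
    if (nN > 0L) {
      lens <- sampleReadLength(nN, config$readLengthWeights)
      noise <- data.frame(
        chrom = names(sim$genome)[1],
        fivePrime = sample(seq(50L, chrLen - 50L), nN, replace = TRUE),
        strand = sample(c("+", "-"), nN, replace = TRUE), length = lens,
        treatment = sample(c("LTM", "CHX"), nN, replace = TRUE,
                           prob = c(0.5, 0.5)), stringsAsFactors = FALSE)
      out <- rbind(out, noise)
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate light/heavy acetyl precursor intensity pairs
#'
#' Draws \code{n} log-normal intensity pairs whose light fraction has
#' expectation \code{degree}/100 with coefficient of variation
#' \code{cv}. A planted degree of 100 gives heavy intensity exactly 0,
#' and 0 gives light intensity exactly 0. Uses the current RNG state.
#'
#' @param degree Planted degree of NTA in percent.
#' @param n Number of pairs.
#' @param cv Coefficient of variation of the channel intensities.
#' @param meanIntensity Mean total precursor intensity.
#' @return \code{data.frame} with \code{intensity_light},
#'   \code{intensity_heavy}.
#' @export
simulateIntensityPairs <- function(degree, n, cv = 0.1,
                                   meanIntensity = 1e6) {
  stopifnot(degree >= 0, degree <= 100, n >= 1)
  d <- degree / 100
  tot <- rlnorm(n, meanlog = log(meanIntensity), sdlog = 0.3)
  sdl <- sqrt(log(1 + cv^2))
  noiseL <- exp(rnorm(n, -sdl^2 / 2, sdl))
  noiseH <- exp(rnorm(n, -sdl^2 / 2, sdl))
  data.frame(intensity_light = tot * d * noiseL,
             intensity_heavy = tot * (1 - d) * noiseH)
}

cleaveAfter <- list(trypsin = c("K", "R"), gluc = c("E", "D"))

ntermPeptide <- function(proteoformSeq, enzyme, minLen = 7L, maxLen = 30L) {
  res <- strsplit(proteoformSeq, "")[[1]]
  sites <- which(res %in% cleaveAfter[[enzyme]])
  sites <- sites[sites >= minLen]
  end <- if (length(sites)) min(sites[1], maxLen) else min(length(res), maxLen)
  substr(proteoformSeq, 1L, end)
}

#' Simulate an N-terminal PSM table with intensities and predictions
#'
#' Generates N-terminal peptides from the planted proteoforms after
#' applying the iMet-excision rule, assigns light-acetyl versus
#' in-vitro heavy-acetyl modification states stochastically at the
#' planted degree of the N-terminus, emits ragged stromal neo-termini
#' at planted cleavage sites, attaches light/heavy intensity pairs with
#' expectation equal to the planted degree, and appends decoy records
#' with q-values above 0.01. Also emits TargetP-style predictions and a
#' consensus-localization table for all annotated proteins.
#'
#' @param sim Output of \code{\link{simulateGenome}}.
#' @param config The same \code{\link{simConfig}}.
#' @return A list with \code{psms}, \code{targetp}, \code{localization}
#'   data.frames.
#' @export
simulatePsmTable <- function(sim, config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed + 2L)
  truth <- sim$truth
  prots <- truth$proteoforms
  annSeq <- prots$sequence[prots$relation == "annotated"]
  names(annSeq) <- prots$protein[prots$relation == "annotated"]
  rows <- list()
  for (i in seq_len(nrow(truth$ntermini))) {
    nt <- truth$ntermini[i, ]
    parent <- annSeq[[nt$protein]]
    # proteoform sequence viewed from this N-terminus
    ntSeq <- if (substr(nt$residues, 1L, 1L) == "M")
      paste0("M", substr(parent, nt$start + 1L, nchar(parent)))
      else substr(parent, nt$start, nchar(parent))
    for (enz in config$enzymeSet) {
      pep <- ntermPeptide(ntSeq, enz)
      if (nchar(pep) < 7L) next
      n <- config$psmPerNterm
      nNTA <- rbinom(1L, n, nt$degree / 100)
      mods <- c(rep("light_acetyl", nNTA), rep("free_heavy", n - nNTA))
      pairs <- simulateIntensityPairs(nt$degree, n, config$intensityNoiseCV)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, protein = nt$protein, start = nt$start,
        modification = mods, enzyme = enz,
        q_value = runif(n, 0, 0.009),
        intensity_light = pairs$intensity_light,
        intensity_heavy = pairs$intensity_heavy, stringsAsFactors = FALSE)
    }
  }
  psms <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(), protein = character(),
               start = integer(), modification = character(),
               enzyme = character(), q_value = numeric(),
               intensity_light = numeric(), intensity_heavy = numeric(),
               stringsAsFactors = FALSE)
  # decoys fail the q-value filter
  nDecoy <- round(config$decoyFraction * nrow(psms))
  if (nDecoy > 0L) {
    decoys <- data.frame(
      peptide = vapply(seq_len(nDecoy), function(k)
        paste(sample(AA20, 10L, replace = TRUE), collapse = ""), ""),
      protein = sprintf("DECOY_%03d", seq_len(nDecoy)),
      start = sample(5:50, nDecoy, replace = TRUE),
      modification = "unmodified", enzyme = "trypsin",
      q_value = runif(nDecoy, 0.011, 0.5),
      intensity_light = NA_real_, intensity_heavy = NA_real_,
      stringsAsFactors = FALSE)
    psms <- rbind(psms, decoys)
  }
  rownames(psms) <- NULL
  proteins <- names(annSeq)
  cl <- truth$cleavages
  targetp <- data.frame(
    protein = proteins,
    prediction = ifelse(proteins %in% cl$protein,
                        cl$prediction[match(proteins, cl$protein)], "noTP"),
    site = ifelse(proteins %in% cl$protein,
                  cl$site[match(proteins, cl$protein)], NA_integer_),
    stringsAsFactors = FALSE)
  localization <- data.frame(
    protein = proteins,
    compartment = ifelse(targetp$prediction == "cTP", "chloroplast",
                  ifelse(targetp$prediction == "mTP", "mitochondrion",
                         "cytosol")), stringsAsFactors = FALSE)
  list(psms = psms, targetp = targetp, localization = localization)
}
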
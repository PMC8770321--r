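# Hand-built toy transcript models used across tests.
#
# Gene A (+ strand, one intron):
#   genomic 1..40  : exon1 (tx 1..40)
#   genomic 41..60 : intron
#   genomic 61..100: exon2 (tx 41..80)
#   CDS tx 21..50 (10 codons)
# Gene B (- strand, single exon): genomic 121..200, txLen 80, CDS tx 21..50.
toyModels <- function() {
  info <- data.frame(
    transcript = c("txA", "txB"), gene = c("geneA", "geneB"),
    chrom = "chr1", strand = c("+", "-"), txLen = c(80L, 80L),
    cdsStartTx = c(21L, 21L), cdsEndTx = c(50L, 50L),
    stringsAsFactors = FALSE)
  exons <- list(
    txA = data.frame(start = c(1L, 61L), end = c(40L, 100L)),
    txB = data.frame(start = 121L, end = 200L))
  transcriptModels(info, exons)
}

# genome matching toyModels: transcript sequences are planted and the
# chromosome assembled around them
toyGenome <- function(txAseq = NULL, txBseq = NULL) {
  set.seed(42)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  if (is.null(txAseq))
    txAseq <- paste0(strrep("C", 20), "ATG", strrep("GCC", 8), "TAA",
                     strrep("C", 30))
  if (is.null(txBseq))
    txBseq <- paste0(strrep("C", 20), "ATG", strrep("GCC", 8), "TAA",
                     strrep("C", 30))
  stopifnot(nchar(txAseq) == 80L, nchar(txBseq) == 80L)
  intron <- paste0("GT", rnd(16), "AG")
  chr <- paste0(substr(txAseq, 1, 40), intron, substr(txAseq, 41, 80),
                rnd(20),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(txBseq))),
                rnd(50))
  g <- Biostrings::DNAStringSet(chr)
  names(g) <- "chr1"
  g
}

# build a PSiteTrack directly from planted P-site positions
trackFromPsites <- function(df, treatment) {
  counts <- stats::aggregate(count ~ chrom + strand + pos, data = df,
                             FUN = sum)
  counts <- counts[order(counts$chrom, counts$strand, counts$pos), ]
  counts <- counts[c("chrom", "strand", "pos", "count")]
  rownames(counts) <- NULL
  new("PSiteTrack", treatment = treatment, positions = counts,
      nAccepted = as.integer(sum(counts$count)), nRejected = 0L)
}

emptyTrack <- function(treatment) {
  new("PSiteTrack", treatment = treatment,
      positions = data.frame(chrom = character(), strand = character(),
                             pos = integer(), count = integer()),
      nAccepted = 0L, nRejected = 0L)
}

# small simulation configuration used where full-size defaults would be
# wastefully slow
tinyConfig <- function(seed, ...) {
  args <- list(seed = seed, nGenes = 2L, geneLengthRange = c(150L, 240L),
               utr5LengthRange = c(40L, 60L), utr3LengthRange = c(40L, 60L),
               noiseFraction = 0, jitterProb = 0, nIntergenicOrfs = 1L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}
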
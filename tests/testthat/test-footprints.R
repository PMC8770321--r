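test_that("P-site offset table is total on 26-34 nt and undefined elsewhere", {
  for (len in 1:50) {
    off <- psiteOffset(len)
    if (len >= 26 && len <= 30) expect_identical(off, 12L)
    else if (len >= 31 && len <= 33) expect_identical(off, 13L)
    else if (len == 34) expect_identical(off, 14L)
    else expect_true(is.na(off))
  }
})

test_that("P-sites are offset along the transcription direction", {
  expect_identical(assignPSite(100L, "+", 26L), 112L)
  expect_identical(assignPSite(100L, "+", 34L), 114L)
  expect_true(is.na(assignPSite(100L, "+", 25L)))
  # minus strand: 5' end is the rightmost coordinate, offset decreases
  expect_identical(assignPSite(200L, "-", 26L), 188L)
  expect_identical(assignPSite(200L, "-", 34L), 186L)
})

test_that("track building counts accepted reads and reports rejections", {
  empty <- buildTrack(data.frame(chrom = character(), fivePrime = integer(),
                                 strand = character(), length = integer()),
                      "LTM")
  expect_identical(trackTotal(empty), 0L)

  reads <- data.frame(chrom = "chr1", fivePrime = c(100L, 100L, 300L, 10L),
                      strand = "+", length = c(28L, 28L, 30L, 25L))
  tr <- buildTrack(reads, "LTM")
  pos <- trackPositions(tr)
  expect_identical(pos$count[pos$pos == 112], 2L)
  expect_identical(tr@nAccepted + tr@nRejected, nrow(reads))
  expect_identical(tr@nRejected, 1L)  # the 25-nt footprint
  expect_identical(trackTotal(tr), 3L)
})

test_that("track equals a brute-force recount over simulated reads", {
  set.seed(11)
  n <- 1000L
  reads <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    fivePrime = sample(100:5000, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    length = sample(24:36, n, TRUE))
  tr <- buildTrack(reads, "CHX")
  # naive recount
  tally <- list()
  rejected <- 0L
  for (i in seq_len(n)) {
    len <- reads$length[i]
    off <- if (len >= 26 && len <= 30) 12L else if (len <= 33 && len >= 31)
      13L else if (len == 34) 14L else NA_integer_
    if (is.na(off)) { rejected <- rejected + 1L; next }
    p <- if (reads$strand[i] == "+") reads$fivePrime[i] + off
         else reads$fivePrime[i] - off
    key <- paste(reads$chrom[i], reads$strand[i], p)
    tally[[key]] <- (tally[[key]] %||% 0L) + 1L
  }
  expect_identical(tr@nRejected, rejected)
  pos <- trackPositions(tr)
  expect_identical(nrow(pos), length(tally))
  for (i in seq_len(nrow(pos))) {
    key <- paste(pos$chrom[i], pos$strand[i], pos$pos[i])
    expect_identical(pos$count[i], tally[[key]])
  }
})

test_that("strand mirror of genome and reads mirrors the track", {
  set.seed(12)
  L <- 10000L
  reads <- data.frame(chrom = "chr1",
                      fivePrime = sample(500:9500, 200, TRUE),
                      strand = "+", length = sample(26:34, 200, TRUE))
  fwd <- buildTrack(reads, "LTM")
  mirrored <- data.frame(chrom = "chr1",
                         fivePrime = L - reads$fivePrime + 1L,
                         strand = "-", length = reads$length)
  rev <- buildTrack(mirrored, "LTM")
  a <- trackPositions(fwd); b <- trackPositions(rev)
  b$pos <- L - b$pos + 1L
  b <- b[order(b$pos), ]; a <- a[order(a$pos), ]
  expect_equal(a$pos, b$pos)
  expect_equal(a$count, b$count)
})

test_that("offsets resolve in transcript space across exon junctions", {
  models <- toyModels()
  # txA: tx position 35 is genomic 35; a 28-nt read with 5' end there has
  # its P-site at tx 47, which lies in exon 2 at genomic 61 + (47-41) = 67
  reads <- data.frame(chrom = "chr1", fivePrime = 35L, strand = "+",
                      length = 28L)
  tr <- buildTrack(reads, "LTM", models = models)
  expect_identical(trackPositions(tr)$pos, 67L)
  # purely genomic offsetting would land in the intron instead
  trNaive <- buildTrack(reads, "LTM")
  expect_identical(trackPositions(trNaive)$pos, 47L)
})

test_that("unknown chromosomes are rejected with a named record", {
  reads <- data.frame(chrom = c("chr1", "chrX"), fivePrime = c(100L, 100L),
                      strand = "+", length = 28L)
  expect_error(buildTrack(reads, "LTM", chromNames = "chr1"), "chrX")
})

test_that("metagene density normalizes per gene and applies the RPF floor", {
  models <- toyModels()
  # uniform count 2 over txA window (CDS 21..50 plus 20 nt flanks)
  txWin <- 1:70
  gpos <- txToGenome(models, "txA", txWin)
  df <- data.frame(chrom = "chr1", strand = "+", pos = gpos, count = 2L)
  tr <- trackFromPsites(df, "CHX")
  mg <- metageneDensity(tr, models, minReads = 20L)
  expect_true(all(abs(mg$perGene$geneA$norm - 1) < 1e-12))
  expect_true("geneB" %in% names(mg$excluded))  # zero reads
  # 19 mapped RPFs -> excluded
  df19 <- data.frame(chrom = "chr1", strand = "+",
                     pos = txToGenome(models, "txA", 21:39), count = 1L)
  mg19 <- metageneDensity(trackFromPsites(df19, "CHX"), models)
  expect_true("geneA" %in% names(mg19$excluded))
  # aggregate equals naive averaging across genes
  dfB <- data.frame(chrom = "chr1", strand = "-",
                    pos = txToGenome(models, "txB", txWin), count = 4L)
  both <- trackFromPsites(rbind(df, dfB), "CHX")
  mg2 <- metageneDensity(both, models, minReads = 20L)
  naive <- tapply(
    c(mg2$perGene$geneA$norm, mg2$perGene$geneB$norm),
    c(mg2$perGene$geneA$relPos, mg2$perGene$geneB$relPos), mean)
  expect_equal(mg2$aggregate$density,
               as.vector(naive[as.character(mg2$aggregate$relPos)]))
})

test_that("alignment dialects round-trip through the readers", {
  cfg <- tinyConfig(5)
  dir <- withr::local_tempdir()
  simulateAll(cfg, dir)
  tsv <- readAlignments(file.path(dir, "ltm.tsv"))
  sam <- readAlignments(file.path(dir, "ltm.sam"))
  o <- function(x) {
    x <- x[order(x$chrom, x$fivePrime, x$strand, x$length), ]
    rownames(x) <- NULL
    x
  }
  expect_identical(o(tsv), o(sam))
})
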
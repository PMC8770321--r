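# helpers to plant P-sites in transcript coordinates of the toy models
txSpike <- function(models, tx, txPos, count, treatment) {
  row <- txInfo(models)[txInfo(models)$transcript == tx, ]
  data.frame(chrom = row$chrom, strand = row$strand,
             pos = txToGenome(models, tx, txPos), count = count)
}

test_that("normalized score follows R = (X/N) * 10", {
  expect_equal(normalizedScore(5, 1000), 0.05)
  expect_equal(normalizedScore(7, 7), 10)
  expect_equal(normalizedScore(0, 50), 0)
  expect_error(normalizedScore(1, 0))
})

test_that("LTM peaks anchor to start codons within one nucleotide", {
  models <- toyModels()
  genome <- toyGenome()
  th <- tisThresholds()
  # spike exactly on the annotated ATG (tx 21)
  ltm <- trackFromPsites(txSpike(models, "txA", 21L, 10L, "LTM"), "LTM")
  tis <- callTIS(ltm, emptyTrack("CHX"), models, genome, th)
  called <- tis[tis$status == "called", ]
  expect_identical(nrow(called), 1L)
  expect_identical(called$pos, txToGenome(models, "txA", 21L))
  expect_identical(called$category, "dbTIS")
  expect_identical(called$codon, "ATG")
  # spike one nucleotide upstream anchors to the same ATG
  ltm2 <- trackFromPsites(txSpike(models, "txA", 20L, 10L, "LTM"), "LTM")
  tis2 <- callTIS(ltm2, emptyTrack("CHX"), models, genome, th)
  expect_identical(tis2$pos[tis2$status == "called"],
                   txToGenome(models, "txA", 21L))
  # spike nowhere near a start codon yields no call
  ltm3 <- trackFromPsites(txSpike(models, "txA", 33L, 50L, "LTM"), "LTM")
  tis3 <- callTIS(ltm3, emptyTrack("CHX"), models, genome, th)
  expect_identical(sum(tis3$status == "called"), 0L)
})

test_that("only the maximal peak within a 7-nt window survives", {
  # codon 2 of the CDS is the near-cognate ATT (tx 24)
  txAseq <- paste0(strrep("C", 20), "ATG", "ATT", strrep("GCC", 7), "TAA",
                   strrep("C", 30))
  models <- toyModels()
  genome <- toyGenome(txAseq)
  spikes <- rbind(txSpike(models, "txA", 21L, 10L, "LTM"),
                  txSpike(models, "txA", 24L, 7L, "LTM"))
  tis <- callTIS(trackFromPsites(spikes, "LTM"), emptyTrack("CHX"),
                 models, genome)
  called <- tis[tis$status == "called", ]
  expect_identical(nrow(called), 1L)
  expect_identical(called$pos, txToGenome(models, "txA", 21L))
  # equal counts: the ATG anchor wins the window tie
  spikesEq <- rbind(txSpike(models, "txA", 21L, 10L, "LTM"),
                    txSpike(models, "txA", 24L, 10L, "LTM"))
  tisEq <- callTIS(trackFromPsites(spikesEq, "LTM"), emptyTrack("CHX"),
                   models, genome)
  expect_identical(tisEq$codon[tisEq$status == "called"], "ATG")
})

test_that("TIS categories follow transcript anatomy and frame", {
  # ATG at codon 3 of the CDS (tx 27, +6 nt in frame) and in the leader
  # leader uORF: ATG at tx 11 (stop at 17-19); CDS tx 21-50 with an
  # in-frame ATG at codon 3 (tx 27)
  txAseq <- paste0(strrep("C", 10), "ATG", "GCC", "TAA", "C",
                   "ATG", "GCC", "ATG", strrep("GCC", 6), "TAA",
                   strrep("C", 30))
  models <- toyModels()
  genome <- toyGenome(txAseq)
  th <- tisThresholds()
  spikes <- rbind(txSpike(models, "txA", 11L, 20L, "LTM"),   # uORF in leader
                  txSpike(models, "txA", 21L, 20L, "LTM"),   # dbTIS
                  txSpike(models, "txA", 27L, 20L, "LTM"))   # in-frame dTIS
  tis <- callTIS(trackFromPsites(spikes, "LTM"), emptyTrack("CHX"),
                 models, genome, th)
  called <- tis[tis$status == "called", ]
  cat21 <- called$category[called$pos == txToGenome(models, "txA", 21L)]
  cat27 <- called$category[called$pos == txToGenome(models, "txA", 27L)]
  cat11 <- called$category[called$pos == txToGenome(models, "txA", 11L)]
  expect_identical(cat21, "dbTIS")
  expect_identical(cat27, "cds_dTIS_inframe")
  expect_identical(cat11, "leader5")
})

test_that("category thresholds and dbTIS rescue apply", {
  txAseq <- paste0(strrep("C", 20), "ATG", "GCC", "ATG", strrep("GCC", 6),
                   "TAA", strrep("C", 30))  # in-frame ATG at tx 27
  models <- toyModels()
  genome <- toyGenome(txAseq)
  th <- tisThresholds()
  chxCds <- data.frame(chrom = "chr1", strand = "+",
                       pos = txToGenome(models, "txA", seq(21L, 48L, 3L)),
                       count = 100L)
  chx <- trackFromPsites(chxCds, "CHX")
  # dbTIS with 5 counts and rdiff barely 0.01 is called
  ltm <- trackFromPsites(txSpike(models, "txA", 21L, 5L, "LTM"), "LTM")
  tis <- callTIS(ltm, chx, models, genome, th)
  db <- tis[tis$category == "dbTIS" & tis$gene == "geneA", ]
  expect_identical(db$status, "called")
  expect_identical(db$ltmCount, 5L)
  # CDS-internal candidate below 15 counts is rejected despite high rdiff
  ltm14 <- trackFromPsites(txSpike(models, "txA", 27L, 14L, "LTM"), "LTM")
  tis14 <- callTIS(ltm14, emptyTrack("CHX"), models, genome, th)
  expect_false(any(tis14$category == "cds_dTIS_inframe" &
                   tis14$status == "called"))
  ltm15 <- trackFromPsites(txSpike(models, "txA", 27L, 15L, "LTM"), "LTM")
  tis15 <- callTIS(ltm15, emptyTrack("CHX"), models, genome, th)
  expect_true(any(tis15$category == "cds_dTIS_inframe" &
                  tis15$status == "called"))
  # annotated start with no LTM peak but elongating CHX occupancy is rescued
  rescue <- callTIS(emptyTrack("LTM"), chx, models, genome, th)
  resA <- rescue[rescue$gene == "geneA" & rescue$category == "dbTIS", ]
  expect_identical(resA$status, "rescued_dbTIS")
  # without elongating occupancy there is no rescue
  none <- callTIS(emptyTrack("LTM"), emptyTrack("CHX"), models, genome, th)
  expect_identical(nrow(none), 0L)
})

test_that("raising thresholds never adds a called TIS", {
  cfg <- tinyConfig(21, dtisFraction = 1, uorfFraction = 1)
  sim <- simulateGenome(cfg)
  reads <- simulateFootprints(sim, cfg)
  ltm <- buildTrack(reads[reads$treatment == "LTM", ], "LTM",
                    models = sim$models)
  chx <- buildTrack(reads[reads$treatment == "CHX", ], "CHX",
                    models = sim$models)
  base <- callTIS(ltm, chx, sim$models, sim$genome, tisThresholds())
  stricter <- list(
    tisThresholds(dbTIS = c(50, 0.5)),
    tisThresholds(cds_internal = c(50, 3)),
    tisThresholds(leader5 = c(1e6, 10), leader3 = c(1e6, 10),
                  intergenic = c(1e6, 10)),
    tisThresholds(rescueMinChx = 1e9))
  baseKey <- paste(base$chrom, base$strand, base$pos)
  for (th in stricter) {
    res <- callTIS(ltm, chx, sim$models, sim$genome, th)
    expect_true(all(paste(res$chrom, res$strand, res$pos) %in% baseKey))
  }
})

test_that("caller matches the brute-force oracle on random scenarios", {
  for (seed in c(101, 102, 103)) {
    cfg <- tinyConfig(seed, dtisFraction = 0.7, uorfFraction = 0.5,
                      noiseFraction = 0.05, jitterProb = 0.15)
    sim <- simulateGenome(cfg)
    reads <- simulateFootprints(sim, cfg)
    ltm <- buildTrack(reads[reads$treatment == "LTM", ], "LTM",
                      models = sim$models)
    chx <- buildTrack(reads[reads$treatment == "CHX", ], "CHX",
                      models = sim$models)
    got <- tisComparable(callTIS(ltm, chx, sim$models, sim$genome))
    want <- tisComparable(oracleCallTIS(ltm, chx, sim$models, sim$genome))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("at most one TIS is called per 7-nt window and strand", {
  cfg <- tinyConfig(33, dtisFraction = 1, noiseFraction = 0.1)
  sim <- simulateGenome(cfg)
  reads <- simulateFootprints(sim, cfg)
  ltm <- buildTrack(reads[reads$treatment == "LTM", ], "LTM",
                    models = sim$models)
  chx <- buildTrack(reads[reads$treatment == "CHX", ], "CHX",
                    models = sim$models)
  tis <- callTIS(ltm, chx, sim$models, sim$genome)
  for (s in c("+", "-")) {
    p <- sort(tis$pos[tis$strand == s])
    if (length(p) > 1L) expect_true(all(diff(p) > 3L))
  }
})
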
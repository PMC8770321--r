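test_that("degenerate configurations are rejected", {
  expect_error(simConfig(nGenes = 0), "nGenes")
  expect_error(simConfig(dtisFraction = 1.5), "proportion")
  expect_error(simConfig(geneLengthRange = c(300, 200)), "range")
  expect_error(simConfig(readLengthWeights = c(`25` = 1)), "26-34")
  expect_error(simConfig(ntaDegreeByClass = c(NatA = 120)), "percentages")
})

test_that("identical seed and config reproduce byte-identical outputs", {
  cfg <- tinyConfig(81, dtisFraction = 1, ctpFraction = 0.5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateAll(cfg, d1)
  simulateAll(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
})

test_that("planted dTIS honour the configured fraction and frame", {
  cfg0 <- tinyConfig(82, dtisFraction = 0)
  sim0 <- simulateGenome(cfg0)
  expect_false(any(sim0$truth$tis$category == "cds_dTIS_inframe"))
  cfg <- simConfig(seed = 83, nGenes = 20L, dtisFraction = 0.5,
                   noiseFraction = 0, jitterProb = 0)
  sim <- simulateGenome(cfg)
  dtis <- sim$truth$tis[sim$truth$tis$category == "cds_dTIS_inframe", ]
  expect_identical(nrow(dtis),
                   sum(!is.na(sim$truth$tis$imet) & sim$truth$tis$imet > 1L))
  info <- txInfo(sim$models)
  chr <- as.character(sim$genome[[1]])
  for (i in seq_len(nrow(dtis))) {
    row <- info[info$transcript == dtis$transcript[i], ]
    # frame check by brute-force coordinate arithmetic through the exons
    ex <- txExons(sim$models)[[dtis$transcript[i]]]
    map <- integer(0)
    for (j in seq_len(nrow(ex)))
      map <- if (row$strand == "+") c(map, ex$start[j]:ex$end[j])
             else c(map, ex$end[j]:ex$start[j])
    txPos <- match(dtis$pos[i], map)
    expect_identical(txPos, dtis$txPos[i])
    expect_identical((txPos - row$cdsStartTx) %% 3L, 0L)
    # the genomic codon matches the recorded one
    g3 <- map[txPos:(txPos + 2L)]
    bases <- substring(chr, g3, g3)
    if (row$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
    expect_identical(paste(bases, collapse = ""), dtis$codon[i])
    expect_true(dtis$codon[i] %in% startCodons())
  }
})

test_that("noise-free footprints land exactly on planted P-sites", {
  cfg <- tinyConfig(84, dtisFraction = 1, uorfFraction = 1)
  sim <- simulateGenome(cfg)
  reads <- simulateFootprints(sim, cfg)
  ltm <- buildTrack(reads[reads$treatment == "LTM", ], "LTM",
                    models = sim$models)
  planted <- paste(sim$truth$tis$chrom, sim$truth$tis$strand,
                   sim$truth$tis$pos)
  pos <- trackPositions(ltm)
  expect_true(all(paste(pos$chrom, pos$strand, pos$pos) %in% planted))
  expect_identical(ltm@nRejected, 0L)
})

test_that("leaky scanning splits initiation binomially", {
  cfg <- simConfig(seed = 85, nGenes = 15L, dtisFraction = 1,
                   leakyFraction = 0.3, ltmReadsPerTis = 100,
                   noiseFraction = 0, jitterProb = 0)
  sim <- simulateGenome(cfg)
  reads <- simulateFootprints(sim, cfg)
  ltm <- buildTrack(reads[reads$treatment == "LTM", ], "LTM",
                    models = sim$models)
  pos <- trackPositions(ltm)
  tis <- sim$truth$tis
  ok <- 0L; total <- 0L
  for (g in unique(tis$gene[!is.na(tis$gene)])) {
    db <- tis[tis$gene == g & tis$category == "dbTIS", ]
    dt <- tis[tis$gene == g & tis$category == "cds_dTIS_inframe", ]
    if (!nrow(dt)) next
    cnt <- function(p) sum(pos$count[pos$chrom == db$chrom[1] &
                                     pos$strand == db$strand[1] &
                                     pos$pos == p])
    nDb <- cnt(db$pos); nDt <- cnt(dt$pos)
    n <- nDb + nDt
    total <- total + 1L
    sd3 <- 3 * sqrt(n * 0.3 * 0.7)
    if (abs(nDt - n * 0.3) <= sd3) ok <- ok + 1L
  }
  expect_gte(total, 10L)
  expect_gte(ok / total, 0.95)
})

test_that("zero CHX rate yields an empty CHX set", {
  cfg <- tinyConfig(86, chxReadsPerGene = 0)
  sim <- simulateGenome(cfg)
  reads <- simulateFootprints(sim, cfg)
  expect_identical(sum(reads$treatment == "CHX"), 0L)
})

test_that("emitted N-terminal peptides obey the iMet-excision rule", {
  cfg <- tinyConfig(87, nGenes = 10L, dtisFraction = 1, ctpFraction = 0.5)
  sim <- simulateGenome(cfg)
  tab <- simulatePsmTable(sim, cfg)
  truth <- sim$truth
  coTrans <- truth$ntermini[truth$ntermini$origin %in%
                            c("dbTIS", "dTIS", "dual_dTIS_cTP"), ]
  expect_true(all(nmeCompliant(coTrans$residues)))
  # a proteoform whose second residue is small starts at iMet+1
  ann <- truth$proteoforms[truth$proteoforms$relation == "annotated", ]
  for (i in seq_len(nrow(ann))) {
    second <- substr(ann$sequence[i], 2L, 2L)
    rec <- truth$ntermini[truth$ntermini$protein == ann$protein[i] &
                          truth$ntermini$origin == "dbTIS", ]
    if (second %in% nmeSmallResidues()) {
      expect_identical(rec$start, 2L)
      expect_identical(rec$residues, second)
    } else {
      expect_identical(rec$start, 1L)
    }
  }
})

test_that("planted degree 100 emits acetyl PSMs with zero heavy intensity", {
  cfg <- tinyConfig(88, nGenes = 6L, dtisFraction = 0, ctpFraction = 0,
                    ntaDegreeByClass = c(NatA = 100, NatB = 100,
                                         NatCEF = 100, refractory = 100,
                                         none = 100))
  sim <- simulateGenome(cfg)
  tab <- simulatePsmTable(sim, cfg)
  true <- tab$psms[!grepl("^DECOY", tab$psms$protein), ]
  expect_true(all(true$modification == "light_acetyl"))
  expect_true(all(true$intensity_heavy == 0))
  expect_true(all(true$intensity_light > 0))
})

test_that("decoy records carry failing q-values at the configured rate", {
  cfg <- tinyConfig(89, nGenes = 10L, dtisFraction = 1, decoyFraction = 0.1)
  tab <- simulatePsmTable(simulateGenome(cfg), cfg)
  nTrue <- sum(!grepl("^DECOY", tab$psms$protein))
  nDecoy <- sum(grepl("^DECOY", tab$psms$protein))
  expect_identical(nDecoy, as.integer(round(0.1 * nTrue)))
  expect_true(all(tab$psms$q_value[grepl("^DECOY", tab$psms$protein)] > 0.01))
})
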
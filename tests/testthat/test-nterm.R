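psmRow <- function(peptide, protein = "P1", start = 1L,
                   modification = "light_acetyl", enzyme = "trypsin",
                   q = 0.001) {
  data.frame(peptide = peptide, protein = protein, start = start,
             modification = modification, enzyme = enzyme, q_value = q,
             stringsAsFactors = FALSE)
}

test_that("PSM filtering applies the q-value and evidence thresholds", {
  psms <- rbind(psmRow("TDTK", q = 0.001), psmRow("TDTK", q = 0.02),
                psmRow("SSSK", protein = "P2", q = 0.005))
  out <- filterPsms(psms)
  expect_identical(out$nRejected, 1L)
  expect_identical(nrow(out$psms), 2L)
  # single-PSM N-termini are flagged, not dropped
  expect_true(all(out$psms$lowEvidence))
  many <- filterPsms(do.call(rbind, replicate(10, psmRow("TDTK"),
                                              simplify = FALSE)),
                     qMax = 1, minPsm = 1)
  expect_identical(nrow(many$psms), 10L)
  expect_false(any(many$psms$lowEvidence))
})

test_that("N-termini collapse to the longest peptide variant", {
  psms <- rbind(psmRow("TDTKDAGMDAVQR", enzyme = "trypsin"),
                psmRow("TDTKDAGMDAVQRRL", enzyme = "chymotrypsin"),
                psmRow("TDTKDAGMDAVQRRLFE", enzyme = "gluc",
                       modification = "free_heavy"))
  psms$start <- 52L
  rec <- collapseNterm(filterPsms(psms, minPsm = 1)$psms)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$peptide, "TDTKDAGMDAVQRRLFE")
  expect_identical(rec$psmTotal, 3L)
  expect_identical(rec$psmNTA, 2L)
  expect_identical(rec$psmFree, 1L)
  # counts equal a brute-force group-by on a simulated table
  cfg <- tinyConfig(51, dtisFraction = 1, ctpFraction = 1)
  tab <- simulatePsmTable(simulateGenome(cfg), cfg)
  filt <- filterPsms(tab$psms)$psms
  recs <- collapseNterm(filt)
  expect_identical(sum(recs$psmTotal), nrow(filt))
  for (i in sample(nrow(recs), min(10, nrow(recs)))) {
    idx <- filt$protein == recs$protein[i] & filt$start == recs$start[i]
    expect_identical(recs$psmTotal[i], sum(idx))
    expect_identical(recs$psmNTA[i],
                     sum(idx & filt$modification == "light_acetyl"))
  }
})

test_that("conflicting residues at one start are an error", {
  psms <- rbind(psmRow("TDTK"), psmRow("TDAKDAG"))
  expect_error(collapseNterm(filterPsms(psms, minPsm = 1)$psms),
               "conflicting residues")
})

test_that("NME compliance follows MetAP specificity", {
  expect_true(nmeCompliant("T"))     # small residue exposed
  expect_false(nmeCompliant("K"))    # bulky residue exposed
  expect_true(nmeCompliant("MD"))    # retained Met before acidic residue
  expect_false(nmeCompliant("MS"))   # strict: small residue 2 => excision
  expect_true(nmeCompliant("MS", mode = "lenient"))
})

test_that("NME and NAT rule tables are total over the 20 amino acids", {
  small <- nmeSmallResidues()
  rules <- natRuleTable()
  for (aa in c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y")) {
    # exposed position (after iMet excision)
    expect_identical(nmeCompliant(aa, interpret = "exposed"),
                     aa %in% small)
    expClass <- if (aa == "P") "refractory"
                else if (aa %in% rules$natA) "NatA" else "none"
    expect_identical(natClass(aa), expClass)
    # residue 2 behind a retained iMet
    ret <- paste0("M", aa)
    expect_identical(nmeCompliant(ret), !(aa %in% small))
    retClass <- if (aa %in% rules$natB) "NatB"
                else if (aa %in% rules$natCEF) "NatCEF"
                else if (aa == "P") "refractory" else "none"
    expect_identical(natClass(ret), retClass)
  }
})

test_that("NAT classes match the canonical substrate examples", {
  expect_identical(natClass(c("S", "ME", "MK", "P")),
                   c("NatA", "NatB", "NatCEF", "refractory"))
})

test_that("origin classification applies precedence and NME demotion", {
  recs <- data.frame(
    protein = "P1",
    start = c(2L, 53L, 40L, 70L, 90L),
    peptide = c("DAGMDAVQR",      # annotated position 2 -> dbTIS
                "TDTKDAGR",       # dTIS iMet 52 + 1, exposed T -> dTIS
                "KDAGMDAR",       # dTIS match but bulky K -> demoted
                "ASSLK",          # cleavage match only -> cTP_neo
                "GQDLK"),         # nothing -> internal_neo
    psmTotal = 2L, psmNTA = c(2L, 2L, 0L, 1L, 0L), psmFree = 0L,
    lowEvidence = FALSE, stringsAsFactors = FALSE)
  recs$psmFree <- recs$psmTotal - recs$psmNTA
  dtis <- data.frame(protein = "P1", imet = c(52L, 39L), codon = "ATG")
  cleav <- data.frame(protein = "P1", start = 70L, prediction = "cTP")
  out <- classifyOrigin(recs, dtis, cleav)
  expect_identical(out$origin,
                   c("dbTIS", "dTIS", "internal_neo", "cTP_neo",
                     "internal_neo"))
  expect_false(out$nmeCompliant[3])
})

test_that("a dTIS coinciding with a predicted cleavage is labelled dual", {
  recs <- data.frame(protein = "P1", start = 64L, peptide = "ASSLGK",
                     psmTotal = 3L, psmNTA = 2L, psmFree = 1L,
                     lowEvidence = FALSE, stringsAsFactors = FALSE)
  dtis <- data.frame(protein = "P1", imet = 63L, codon = "ATG")
  cleav <- data.frame(protein = "P1", start = 64L, prediction = "cTP")
  out <- classifyOrigin(recs, dtis, cleav)
  expect_identical(out$origin, "dual_dTIS_cTP")
})

test_that("every retained N-terminus receives exactly one origin", {
  cfg <- tinyConfig(55, dtisFraction = 1, ctpFraction = 0.6,
                    mtpFraction = 0.4)
  sim <- simulateGenome(cfg)
  tab <- simulatePsmTable(sim, cfg)
  recs <- collapseNterm(filterPsms(tab$psms)$psms)
  dtis <- sim$truth$tis[sim$truth$tis$category == "cds_dTIS_inframe",
                        c("transcript", "imet")]
  names(dtis)[1] <- "protein"
  dtis$codon <- "ATG"
  matches <- matchCleavage(recs, tab$targetp)
  out <- classifyOrigin(recs, dtis, matches)
  expect_false(anyNA(out$origin))
  expect_true(all(out$origin %in% c("dbTIS", "dTIS", "cTP_neo", "mTP_neo",
                                    "dual_dTIS_cTP", "internal_neo")))
})

test_that("refractory N-termini observed acetylated are flagged not dropped", {
  recs <- data.frame(protein = "P9", start = 2L, peptide = "PDAGK",
                     psmTotal = 2L, psmNTA = 1L, psmFree = 1L,
                     lowEvidence = FALSE, stringsAsFactors = FALSE)
  out <- classifyOrigin(recs)
  expect_true(out$ntaFlag)
  expect_identical(out$origin, "dbTIS")
})
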
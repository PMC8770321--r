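#' Assemble a pipeline run configuration
#'
#' Collects input paths and stage options into a serializable list
#' embedded verbatim in the run report.
#'
#' @param genomeFasta,gff,ltm,chx,psms,targetp,localization Input file
#'   paths (alignments in SAM/BAM or the tabular dialect).
#' @param outDir Output directory.
#' @param thresholds \code{\link{tisThresholds}}.
#' @param qMax,minPsm PSM filtering options.
#' @param nmeMode \code{"strict"} or \code{"lenient"} iMet-retention
#'   rule.
#' @param cleavageWindow,cleavageInclusive Transit-peptide matching
#'   window and its boundary semantics.
#' @param compartment Consensus localization required for
#'   representative cleavage selection.
#' @param degreeMethod \code{"sum"} or \code{"mean"} pair aggregation.
#' @param minProteoformLength Minimum database entry length.
#' @return A list of class \code{"runConfig"}.
#' @export
runConfig <- function(genomeFasta, gff, ltm, chx, psms = NULL,
                      targetp = NULL, localization = NULL,
                      outDir = tempfile("riboNterm_run"),
                      thresholds = tisThresholds(), qMax = 0.01,
                      minPsm = 2L, nmeMode = "strict", cleavageWindow = 5L,
                      cleavageInclusive = TRUE, compartment = "chloroplast",
                      degreeMethod = "sum", minProteoformLength = 7L) {
  cfg <- as.list(environment())
  class(cfg) <- "runConfig"
  cfg
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full riboproteogenomics pipeline
#'
#' Executes footprint P-site assignment, TIS calling, proteoform
#' database construction, N-terminal PSM classification, NTA
#' quantification and cleavage annotation, writing all stage outputs
#' plus a machine-readable JSON report of per-stage record counts and
#' category breakdowns. An empty or absent PSM table skips the
#' proteomics stages with a warning and empty outputs.
#'
#' @param config A \code{\link{runConfig}}.
#' @return Invisibly, a list with the report and the main in-memory
#'   results (\code{tis}, \code{db}, \code{records}, \code{degrees},
#'   \code{classSummary}, \code{representatives}, \code{motif}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outDir, f)
  report <- list(config = unclass(config)[!vapply(config, is.null,
                                                  logical(1))])
  report$config$thresholds <- unclass(config$thresholds)

  genome <- stageTry("genome", Biostrings::readDNAStringSet(config$genomeFasta))
  names(genome) <- sub("\\s.*", "", names(genome))
  models <- stageTry("annotation", readTranscriptModels(config$gff))
  report$annotation <- list(transcripts = nrow(txInfo(models)),
                            genes = length(unique(txInfo(models)$gene)))

  ltm <- stageTry("footprints", {
    r <- readAlignments(config$ltm)
    buildTrack(r, "LTM", models = models, chromNames = names(genome))
  })
  chx <- stageTry("footprints", {
    r <- readAlignments(config$chx)
    buildTrack(r, "CHX", models = models, chromNames = names(genome))
  })
  report$footprints <- list(
    ltm = list(accepted = ltm@nAccepted, rejected = ltm@nRejected),
    chx = list(accepted = chx@nAccepted, rejected = chx@nRejected))
  exportTrackBedGraph(ltm, p("ltm"))
  exportTrackBedGraph(chx, p("chx"))
  for (tr in list(ltm, chx)) {
    mg <- metageneDensity(tr, models)
    write.table(mg$aggregate, p(sprintf("metagene_%s.tsv",
                                        tolower(treatment(tr)))),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  tis <- stageTry("tis_caller",
                  callTIS(ltm, chx, models, genome, config$thresholds))
  writeTisTable(tis, p("called_tis.tsv"))
  report$tis <- list(called = nrow(tis),
                     byCategory = as.list(table(tis$category)),
                     rescued = sum(tis$status == "rescued_dbTIS"))

  db <- stageTry("proteoform_db",
                 buildProteoformDb(models, genome, tis,
                                   minLength = config$minProteoformLength))
  writeProteoformDb(db, p("proteoform_db.fasta"), p("proteoform_db_map.tsv"))
  report$proteoformDb <- list(entries = length(db$sequences),
                              byRelation = as.list(table(db$mapping$relation)))

  psms <- NULL
  if (!is.null(config$psms) && file.exists(config$psms)) {
    psms <- stageTry("nterm_classifier", readPsmTable(config$psms))
  }
  if (is.null(psms) || !nrow(psms)) {
    warning("no PSMs supplied; proteomics stages emit empty outputs")
    records <- collapseNterm(filterPsms(data.frame(
      peptide = character(), protein = character(), start = integer(),
      modification = character(), enzyme = character(),
      q_value = numeric()))$psms)
    degrees <- aggregateDegrees(data.frame(
      protein = character(), start = integer(),
      intensity_light = numeric(), intensity_heavy = numeric()))
    summary <- classSummary(degrees, records)
    reps <- matches <- NULL
    motif <- NULL
    records$nmeCompliant <- logical(0); records$natClass <- character(0)
    records$origin <- character(0)
  } else {
    filt <- stageTry("nterm_classifier",
                     filterPsms(psms, qMax = config$qMax,
                                minPsm = config$minPsm))
    records <- stageTry("nterm_classifier", collapseNterm(filt$psms))
    # dTIS positions in parent-protein residue coordinates
    map <- db$mapping
    dmap <- map[map$relation == "truncated_dTIS" & !is.na(map$parentOffset), ,
                drop = FALSE]
    dtis <- data.frame(protein = dmap$transcript,
                       imet = dmap$parentOffset + 1L,
                       codon = dmap$codon, stringsAsFactors = FALSE)
    matches <- NULL
    if (!is.null(config$targetp) && file.exists(config$targetp)) {
      preds <- stageTry("cleavage_annotator", readTargetP(config$targetp))
      matches <- stageTry("cleavage_annotator",
                          matchCleavage(records, preds,
                                        window = config$cleavageWindow,
                                        inclusive = config$cleavageInclusive))
    }
    records <- stageTry("nterm_classifier",
                        classifyOrigin(records, dtis = dtis,
                                       cleavages = matches,
                                       nmeMode = config$nmeMode))
    pairs <- filt$psms[!is.na(filt$psms$intensity_light %||%
                              rep(NA_real_, nrow(filt$psms))), , drop = FALSE]
    degrees <- stageTry("nta_quant",
                        aggregateDegrees(pairs, method = config$degreeMethod))
    summary <- stageTry("nta_quant", classSummary(degrees, records))
    reps <- NULL; motif <- NULL
    if (!is.null(matches) && !is.null(config$localization) &&
        file.exists(config$localization)) {
      loc <- stageTry("cleavage_annotator",
                      readLocalization(config$localization))
      reps <- stageTry("cleavage_annotator",
                       selectRepresentative(matches, loc,
                                            compartment = config$compartment))
      repSites <- reps[reps$isRepresentative, , drop = FALSE]
      annSeqs <- db$sequences[names(db$sequences) %in% records$protein |
                              names(db$sequences) %in% repSites$protein]
      if (nrow(repSites))
        motif <- stageTry("cleavage_annotator",
                          motifMatrix(repSites, annSeqs))
    }
  }
  writeNtermTable(records, p("ntermini.tsv"))
  write.table(degrees, p("nta_degrees.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(summary, p("nta_class_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(matches))
    write.table(matches, p("cleavage_matches.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(reps))
    write.table(reps, p("cleavage_representatives.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(motif)) writeMotifMatrix(motif, p("cleavage_motif.tsv"))

  report$ntermini <- list(
    records = nrow(records),
    byOrigin = if (nrow(records)) as.list(table(records$origin)) else list(),
    nmeCompliant = sum(records$nmeCompliant %||% logical(0), na.rm = TRUE))
  report$nta <- list(quantified = nrow(degrees),
                     skippedPairs = attr(degrees, "nSkipped") %||% 0L)
  report$cleavage <- list(
    matches = if (is.null(matches)) 0L else nrow(matches),
    representatives = if (is.null(reps)) 0L else sum(reps$isRepresentative))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(list(report = report, tis = tis, db = db, records = records,
                 degrees = degrees, classSummary = summary,
                 representatives = reps, motif = motif))
}
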
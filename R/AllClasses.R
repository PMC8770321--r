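#' @import methods
#' @importFrom stats rpois runif rlnorm rbinom median quantile sd rnorm
#' @importFrom utils read.delim write.table head tail
NULL

#' Strand-aware per-position ribosome P-site count track
#'
#' Holds the positional scores of one ribosome-profiling treatment (LTM,
#' freezing initiating ribosomes, or CHX, freezing elongating ribosomes):
#' for every genomic position carrying at least one accepted footprint,
#' the number of footprints whose P-site was assigned there.
#'
#' @slot treatment Either \code{"LTM"} or \code{"CHX"}.
#' @slot positions A \code{data.frame} with columns \code{chrom},
#'   \code{strand}, \code{pos} (1-based genomic coordinate of the P-site)
#'   and \code{count}.
#' @slot nAccepted Number of reads whose P-site was assigned.
#' @slot nRejected Number of reads rejected (footprint length outside
#'   26--34 nt).
#'
#' @export
setClass("PSiteTrack",
  representation(treatment = "character", positions = "data.frame",
                 nAccepted = "integer", nRejected = "integer"))

setValidity("PSiteTrack", function(object) {
  msg <- character()
  if (!object@treatment %in% c("LTM", "CHX"))
    msg <- c(msg, "treatment must be 'LTM' or 'CHX'")
  pos <- object@positions
  need <- c("chrom", "strand", "pos", "count")
  if (!all(need %in% names(pos)))
    msg <- c(msg, sprintf("positions must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(pos) && any(pos$count < 0))
      msg <- c(msg, "all counts must be >= 0")
    if (nrow(pos) && !all(pos$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (sum(pos$count) != object@nAccepted)
      msg <- c(msg, "track mass must equal the number of accepted reads")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PSiteTrack-class total P-site count in the track
#' @param x,object A \code{PSiteTrack}.
#' @export
setGeneric("trackTotal", function(x) standardGeneric("trackTotal"))

#' @rdname PSiteTrack-class
#' @export
setMethod("trackTotal", "PSiteTrack", function(x) sum(x@positions$count))

#' @describeIn PSiteTrack-class treatment label accessor
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))

#' @rdname PSiteTrack-class
#' @export
setMethod("treatment", "PSiteTrack", function(x) x@treatment)

#' @describeIn PSiteTrack-class per-position counts as a data.frame
#' @export
setGeneric("trackPositions", function(x) standardGeneric("trackPositions"))

#' @rdname PSiteTrack-class
#' @export
setMethod("trackPositions", "PSiteTrack", function(x) x@positions)

setMethod("show", "PSiteTrack", function(object) {
  cat("PSiteTrack (", object@treatment, ")\n", sep = "")
  cat("  ", nrow(object@positions), " positions, ",
      sum(object@positions$count), " P-sites (",
      object@nRejected, " reads rejected)\n", sep = "")
})

#' Transcript models with transcript/genome coordinate maps
#'
#' A compact container for spliced transcript structures: per-transcript
#' exon chains (sorted 5' to 3' in transcript orientation) plus the CDS
#' interval in transcript coordinates, from which 5' leader, CDS and
#' 3' leader intervals derive.
#'
#' @slot txInfo \code{data.frame} with one row per transcript: columns
#'   \code{transcript}, \code{gene}, \code{chrom}, \code{strand},
#'   \code{txLen}, \code{cdsStartTx}, \code{cdsEndTx} (1-based transcript
#'   coordinates; \code{NA} for non-coding models).
#' @slot exons Named list (by transcript) of \code{data.frame}s with
#'   genomic \code{start}/\code{end} (1-based, inclusive), rows ordered
#'   5' to 3' in transcript orientation.
#'
#' @export
setClass("TranscriptModels",
  representation(txInfo = "data.frame", exons = "list"))

setValidity("TranscriptModels", function(object) {
  msg <- character()
  info <- object@txInfo
  need <- c("transcript", "gene", "chrom", "strand", "txLen",
            "cdsStartTx", "cdsEndTx")
  if (!all(need %in% names(info)))
    return(sprintf("txInfo must have columns %s", paste(need, collapse = ", ")))
  if (!setequal(info$transcript, names(object@exons)))
    msg <- c(msg, "exons must be named by the transcripts in txInfo")
  for (tx in info$transcript) {
    ex <- object@exons[[tx]]
    if (is.null(ex)) next
    w <- sum(ex$end - ex$start + 1L)
    if (w != info$txLen[info$transcript == tx])
      msg <- c(msg, sprintf("exon widths of %s do not sum to txLen", tx))
    if (nrow(ex) > 1L) {
      sorted <- all(diff(ex$start) > 0) || all(diff(ex$start) < 0)
      if (!sorted)
        msg <- c(msg, sprintf("exons of %s are not sorted", tx))
      ir <- IRanges::IRanges(ex$start, ex$end)
      if (sum(IRanges::width(IRanges::reduce(ir))) != w)
        msg <- c(msg, sprintf("exons of %s overlap", tx))
    }
  }
  cds <- !is.na(info$cdsStartTx)
  bad <- cds & ((info$cdsEndTx - info$cdsStartTx + 1L) %% 3L != 0L)
  if (any(bad))
    msg <- c(msg, sprintf("CDS length not divisible by 3 for %s",
                          paste(info$transcript[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "TranscriptModels", function(object) {
  cat("TranscriptModels:", nrow(object@txInfo), "transcripts,",
      length(unique(object@txInfo$gene)), "genes\n")
})

#' @describeIn TranscriptModels-class transcript summary table accessor
#' @param x A \code{TranscriptModels} object.
#' @export
setGeneric("txInfo", function(x) standardGeneric("txInfo"))

#' @rdname TranscriptModels-class
#' @export
setMethod("txInfo", "TranscriptModels", function(x) x@txInfo)

#' @describeIn TranscriptModels-class exon chains accessor
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))

#' @rdname TranscriptModels-class
#' @export
setMethod("txExons", "TranscriptModels", function(x) x@exons)
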
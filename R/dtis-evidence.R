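#' Curated Arabidopsis dTIS N-terminus evidence
#'
#' Loads the bundled set of 68 experimentally supported Arabidopsis
#' thaliana N-terminally truncated proteoforms: for each gene the
#' downstream TIS position (with near-cognate start-codon annotation
#' where the initiator is not AUG) and the observed N-terminal peptide
#' evidence string (\code{Ac-} = in vivo acetylated, \code{NH2-} = in
#' vivo free, \code{NH2/Ac-} = both forms observed; the residues that
#' follow are the mature N-terminus, a leading \code{M} marking a
#' retained initiator Met).
#'
#' @return \code{data.frame} with columns \code{gene},
#'   \code{description}, \code{dtis}, \code{nterm}, \code{group}.
#' @export
dtisNtermEvidence <- function() {
  path <- system.file("extdata", "dtis_ntermini_arabidopsis.tsv",
                      package = "riboNterm", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Parse a dTIS position annotation
#'
#' Annotations look like \code{"Met45"} (AUG initiator at residue 45)
#' or \code{"Thr105(ACG)->Met"} (near-cognate ACG at residue 105,
#' decoded as Met).
#'
#' @param x Character vector of annotations.
#' @return \code{data.frame} with columns \code{position} and
#'   \code{codon}.
#' @export
parseDtisPosition <- function(x) {
  m <- regmatches(x, regexec(
    "^([A-Z][a-z]{2})([0-9]+)(\\(([ACGT]{3})\\)->Met)?$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("unparseable dTIS annotation: ",
                     paste(x[bad], collapse = ", "))
  data.frame(
    position = as.integer(vapply(m, `[`, "", 3L)),
    codon = ifelse(vapply(m, `[`, "", 5L) == "", "ATG",
                   vapply(m, `[`, "", 5L)),
    stringsAsFactors = FALSE)
}

#' Parse an N-terminus evidence string
#'
#' @param x Character vector like \code{"Ac-T"}, \code{"NH2-MR"} or
#'   \code{"NH2/Ac-MK"}.
#' @return \code{data.frame} with columns \code{residues} (mature
#'   N-terminal residues, leading \code{M} = retained iMet),
#'   \code{acetylated} and \code{free} (logical evidence flags).
#' @export
parseNtermEvidence <- function(x) {
  m <- regmatches(x, regexec("^(NH2/Ac|NH2|Ac)-([A-Z]+)$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("unparseable N-terminus annotation: ",
                     paste(x[bad], collapse = ", "))
  state <- vapply(m, `[`, "", 2L)
  data.frame(residues = vapply(m, `[`, "", 3L),
             acetylated = state %in% c("Ac", "NH2/Ac"),
             free = state %in% c("NH2", "NH2/Ac"),
             stringsAsFactors = FALSE)
}

#' Classify curated dTIS N-terminus evidence
#'
#' Runs the NME-compliance and NAT-class rules over a table of (dTIS
#' position, N-terminus) evidence rows, as loaded by
#' \code{\link{dtisNtermEvidence}}.
#'
#' @param evidence \code{data.frame} with columns \code{dtis} and
#'   \code{nterm} (defaults to the bundled curated set).
#' @param nmeMode Passed to \code{\link{nmeCompliant}}.
#' @return The table with added columns \code{position}, \code{codon},
#'   \code{residues}, \code{acetylated}, \code{free},
#'   \code{nmeCompliant}, \code{natClass} and \code{natConsistent}
#'   (acetylation evidence does not contradict the NAT class, i.e. a
#'   refractory N-terminus is not observed acetylated).
#' @export
classifyDtisEvidence <- function(evidence = dtisNtermEvidence(),
                                 nmeMode = "strict") {
  pos <- parseDtisPosition(evidence$dtis)
  nt <- parseNtermEvidence(evidence$nterm)
  out <- cbind(evidence, pos, nt)
  out$nmeCompliant <- nmeCompliant(out$residues, mode = nmeMode)
  out$natClass <- natClass(out$residues)
  out$natConsistent <- !(out$natClass == "refractory" & out$acetylated)
  out
}
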
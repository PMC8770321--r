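#' Filter N-terminal peptide-spectrum matches
#'
#' Keeps PSMs with \code{q_value <= qMax} (default 0.01). N-termini
#' (protein, start groups) supported by fewer than \code{minPsm} PSMs
#' (default 2) are flagged low-evidence rather than dropped, so that the
#' single-PSM acetylation rule ("at least one PSM") can still apply
#' downstream.
#'
#' @param psms \code{data.frame} with columns \code{peptide},
#'   \code{protein}, \code{start} (1-based residue position in the
#'   protein, iMet = 1), \code{modification} (one of
#'   \code{"light_acetyl"}, \code{"free_heavy"}, \code{"unmodified"}),
#'   \code{enzyme}, \code{q_value}; optionally \code{intensity_light},
#'   \code{intensity_heavy}.
#' @param qMax PSM-level q-value cutoff.
#' @param minPsm Minimum PSMs per N-terminus before flagging.
#' @return List with \code{psms} (retained, with a \code{lowEvidence}
#'   flag) and \code{nRejected}.
#' @export
filterPsms <- function(psms, qMax = 0.01, minPsm = 2L) {
  stopifnot(all(c("peptide", "protein", "start", "modification",
                  "q_value") %in% names(psms)))
  if (nrow(psms) && any(psms$start < 1L, na.rm = TRUE))
    stop("start positions must be >= 1")
  keep <- psms$q_value <= qMax
  out <- psms[keep, , drop = FALSE]
  if (nrow(out)) {
    key <- paste(out$protein, out$start)
    counts <- table(key)
    out$lowEvidence <- as.integer(counts[key]) < minPsm
  } else {
    out$lowEvidence <- logical(0)
  }
  rownames(out) <- NULL
  list(psms = out, nRejected = sum(!keep))
}

#' Collapse N-terminal PSMs to unique protein N-termini
#'
#' PSMs sharing a (protein, start) pair but differing at their C-termini
#' (different digestion enzymes or missed cleavages) are collapsed to
#' the longest peptide variant; PSM counts are summed by modification
#' state. Peptides claiming the same start must agree over their common
#' residues, otherwise an error names the conflicting records.
#'
#' @param psms Filtered PSM \code{data.frame} (see
#'   \code{\link{filterPsms}}).
#' @return \code{data.frame} with one row per N-terminus: \code{protein},
#'   \code{start}, \code{peptide} (longest variant), \code{psmTotal},
#'   \code{psmNTA} (light acetyl), \code{psmFree} (in vitro heavy acetyl
#'   or unmodified), \code{lowEvidence}.
#' @export
collapseNterm <- function(psms) {
  if (!nrow(psms)) {
    return(data.frame(protein = character(), start = integer(),
                      peptide = character(), psmTotal = integer(),
                      psmNTA = integer(), psmFree = integer(),
                      lowEvidence = logical(), stringsAsFactors = FALSE))
  }
  key <- paste(psms$protein, psms$start, sep = "\r")
  groups <- split(seq_len(nrow(psms)), key)
  rows <- lapply(groups, function(idx) {
    g <- psms[idx, , drop = FALSE]
    o <- order(-nchar(g$peptide), g$peptide)
    longest <- g$peptide[o[1]]
    pref <- substring(longest, 1L, nchar(g$peptide)) == g$peptide
    if (!all(pref))
      stop("conflicting residues at ", g$protein[1], " start ", g$start[1],
           ": ", paste(unique(g$peptide[!pref]), collapse = ", "),
           " vs ", longest)
    nta <- sum(g$modification == "light_acetyl")
    data.frame(protein = g$protein[1], start = g$start[1], peptide = longest,
               psmTotal = nrow(g), psmNTA = nta, psmFree = nrow(g) - nta,
               lowEvidence = all(g$lowEvidence %||% FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Initiator-methionine-excision compliance of an N-terminus
#'
#' Met aminopeptidases excise the iMet when the second residue is small
#' (\code{\link{nmeSmallResidues}}). An N-terminus starting at iMet+1 is
#' therefore compliant iff the exposed residue is small; an N-terminus
#' retaining the iMet is compliant (in strict mode) iff residue 2 is
#' \emph{not} small, since a small residue 2 should have led to
#' excision. Lenient mode accepts all retained-Met termini.
#'
#' @param residues Character vector of N-terminal residue strings: with
#'   \code{interpret = "auto"} a terminus starting with \code{"M"} is
#'   treated as iMet-retained and judged on its second residue; any
#'   other first residue is treated as the residue exposed after iMet
#'   excision. \code{"exposed"}/\code{"retained"} force one reading
#'   (for \code{"retained"} the relevant residue is residue 2, i.e.
#'   pass \code{"MX"} or just \code{"X"}).
#' @param mode \code{"strict"} (default) or \code{"lenient"}.
#' @param interpret Positional interpretation, see \code{residues}.
#' @param smallResidues Rule table; defaults to
#'   \code{\link{nmeSmallResidues}}.
#' @return Logical vector.
#' @examples
#' nmeCompliant(c("T", "K", "MD", "MS"))
#' # TRUE FALSE TRUE FALSE (strict mode)
#' @export
nmeCompliant <- function(residues, mode = c("strict", "lenient"),
                         interpret = c("auto", "exposed", "retained"),
                         smallResidues = nmeSmallResidues()) {
  mode <- match.arg(mode)
  interpret <- match.arg(interpret)
  first <- substr(residues, 1L, 1L)
  second <- substr(residues, 2L, 2L)
  retained <- switch(interpret, auto = first == "M",
                     exposed = rep(FALSE, length(residues)),
                     retained = rep(TRUE, length(residues)))
  p2 <- ifelse(retained & first == "M" & second != "", second, first)
  ifelse(retained,
         if (mode == "lenient") TRUE else !(p2 %in% smallResidues),
         first %in% smallResidues)
}

#' N-terminal acetyltransferase class of an N-terminus
#'
#' Applies the NAT substrate rules (\code{\link{natRuleTable}}):
#' iMet-excised termini exposing Ala/Ser/Thr/Val/Gly/Cys are NatA
#' substrates; iMet-retained termini are NatB (acidic/amide residue 2)
#' or NatC/E/F (hydrophobic/basic residue 2) substrates; Pro at the
#' mature first position (or residue 2 of a retained iMet) is
#' refractory to acetylation. Everything else is \code{"none"}.
#'
#' @param residues Character vector of N-terminal residue strings
#'   (leading \code{"M"} means iMet retained).
#' @param rules Rule table, see \code{\link{natRuleTable}}.
#' @return Character vector of classes: \code{"NatA"}, \code{"NatB"},
#'   \code{"NatCEF"}, \code{"refractory"} or \code{"none"}.
#' @examples
#' natClass(c("S", "ME", "MK", "P"))
#' # "NatA" "NatB" "NatCEF" "refractory"
#' @export
natClass <- function(residues, rules = natRuleTable()) {
  vapply(residues, function(r) {
    first <- substr(r, 1L, 1L)
    if (first == "M") {
      second <- substr(r, 2L, 2L)
      if (second %in% rules$natB) "NatB"
      else if (second %in% rules$natCEF) "NatCEF"
      else if (second == "P") "refractory"
      else "none"
    } else {
      if (first == "P") "refractory"
      else if (first %in% rules$natA) "NatA"
      else "none"
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Classify the origin of collapsed protein N-termini
#'
#' Assigns each N-terminus exactly one origin label. Starts at protein
#' position 1 or 2 of an annotated entry are \code{dbTIS}. A start
#' matching a called in-frame downstream TIS at its iMet or iMet+1 that
#' is NME-compliant is \code{dTIS}; when a predicted transit-peptide
#' cleavage also matches the start the record is the ambiguous
#' \code{dual_dTIS_cTP}. Starts matching only a cleavage prediction are
#' \code{cTP_neo}/\code{mTP_neo}; everything else is
#' \code{internal_neo}. A positional dTIS match failing NME (for
#' example a near-cognate start exposing a bulky residue) is demoted to
#' a neo-terminus. Refractory-class N-termini observed acetylated and
#' mitochondrial-cleavage N-termini observed acetylated are flagged,
#' not rejected.
#'
#' @param records Collapsed N-termini from \code{\link{collapseNterm}}.
#' @param dtis \code{data.frame} mapping called in-frame dTIS into
#'   protein coordinates: columns \code{protein}, \code{imet} (residue
#'   index of the dTIS initiator Met in the annotated protein),
#'   \code{codon}.
#' @param cleavages \code{data.frame} of transit-peptide matches from
#'   \code{\link{matchCleavage}} (columns \code{protein}, \code{start},
#'   \code{prediction}).
#' @param nmeMode Passed to \code{\link{nmeCompliant}}.
#' @return \code{records} with added columns \code{nmeCompliant},
#'   \code{natClass}, \code{origin}, \code{ntaFlag} (refractory but
#'   acetylated), \code{mitoNtaFlag} and \code{dtisImet}.
#' @export
classifyOrigin <- function(records, dtis = NULL, cleavages = NULL,
                           nmeMode = "strict") {
  n <- nrow(records)
  res <- records
  res$nmeCompliant <- NA
  res$natClass <- NA_character_
  res$origin <- NA_character_
  res$ntaFlag <- FALSE
  res$mitoNtaFlag <- FALSE
  res$dtisImet <- NA_integer_
  for (i in seq_len(n)) {
    p <- res$protein[i]; s <- res$start[i]
    nterm <- substr(res$peptide[i], 1L, 2L)
    cls <- natClass(nterm)
    res$natClass[i] <- cls
    res$ntaFlag[i] <- cls == "refractory" && res$psmNTA[i] > 0
    if (s <= 2L) {
      res$origin[i] <- "dbTIS"
      res$nmeCompliant[i] <- nmeCompliant(nterm, mode = nmeMode)
      next
    }
    dhit <- if (is.null(dtis) || !nrow(dtis)) integer(0) else
      which(dtis$protein == p & (dtis$imet == s | dtis$imet == s - 1L))
    chit <- if (is.null(cleavages) || !nrow(cleavages)) integer(0) else
      which(cleavages$protein == p & cleavages$start == s)
    dtisOk <- FALSE
    if (length(dhit)) {
      imet <- dtis$imet[dhit[1]]
      res$dtisImet[i] <- imet
      # positional NME: start==imet must retain Met, start==imet+1 must
      # expose a small residue
      nme <- if (s == imet) {
        substr(nterm, 1L, 1L) == "M" &&
          nmeCompliant(nterm, mode = nmeMode)
      } else {
        nmeCompliant(substr(nterm, 1L, 1L), mode = nmeMode)
      }
      res$nmeCompliant[i] <- nme
      dtisOk <- nme
    } else {
      res$nmeCompliant[i] <- nmeCompliant(nterm, mode = nmeMode)
    }
    if (length(chit)) {
      pred <- cleavages$prediction[chit[1]]
      res$mitoNtaFlag[i] <- pred == "mTP" && res$psmNTA[i] > 0
    }
    res$origin[i] <-
      if (dtisOk && length(chit)) "dual_dTIS_cTP"
      else if (dtisOk) "dTIS"
      else if (length(chit)) {
        if (cleavages$prediction[chit[1]] == "mTP") "mTP_neo" else "cTP_neo"
      }
      else "internal_neo"
  }
  res
}

#' Write collapsed, classified N-termini as TSV
#'
#' @param records \code{data.frame} from \code{\link{classifyOrigin}}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeNtermTable <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
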
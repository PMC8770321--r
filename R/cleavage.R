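#' Read a TargetP-style prediction table
#'
#' Tab-separated columns: protein accession, prediction (one of
#' \code{cTP}, \code{mTP}, \code{SP}, \code{luTP}, \code{noTP}) and
#' cleavage-site position (the presequence length, i.e. the P1
#' residue; 0 or NA for \code{noTP}).
#'
#' @param path File path.
#' @return \code{data.frame} with columns \code{protein},
#'   \code{prediction}, \code{site}.
#' @export
readTargetP <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("protein", "prediction", "site")
  df$site <- as.integer(df$site)
  bad <- df$prediction != "noTP" & (is.na(df$site) | df$site < 1L)
  if (any(bad))
    stop("positive predictions need a cleavage site >= 1: ",
         paste(df$protein[bad], collapse = ", "))
  df
}

#' Read a subcellular-localization table
#'
#' Tab-separated columns: protein accession, consensus compartment.
#'
#' @param path File path.
#' @return \code{data.frame} with columns \code{protein},
#'   \code{compartment}.
#' @export
readLocalization <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("protein", "compartment")
  df
}

#' Match N-terminus start positions to predicted cleavage sites
#'
#' An N-terminus matches a transit-peptide prediction when its start
#' position lies within the P5--P5' region of the predicted cleavage
#' site, i.e. \eqn{|start - P1'| \le window} with P1' = site + 1 and
#' window 5 by default. The deviation is signed (negative = upstream of
#' P1'). Set \code{inclusive = FALSE} for the strict reading
#' (deviation strictly smaller than the window).
#'
#' @param starts \code{data.frame} with columns \code{protein},
#'   \code{start}.
#' @param predictions \code{data.frame} from \code{\link{readTargetP}};
#'   rows with prediction \code{noTP} never match.
#' @param window Maximal absolute deviation in residues (default 5).
#' @param inclusive If \code{TRUE} (default) the boundary
#'   \code{|deviation| == window} matches.
#' @return \code{data.frame} with columns \code{protein}, \code{start},
#'   \code{prediction}, \code{site}, \code{p1prime}, \code{deviation};
#'   one row per matched start.
#' @export
matchCleavage <- function(starts, predictions, window = 5L,
                          inclusive = TRUE) {
  preds <- predictions[predictions$prediction != "noTP", , drop = FALSE]
  m <- merge(starts[c("protein", "start")], preds, by = "protein")
  if (!nrow(m)) {
    return(data.frame(protein = character(), start = integer(),
                      prediction = character(), site = integer(),
                      p1prime = integer(), deviation = integer(),
                      stringsAsFactors = FALSE))
  }
  m$p1prime <- m$site + 1L
  m$deviation <- m$start - m$p1prime
  hit <- if (inclusive) abs(m$deviation) <= window
         else abs(m$deviation) < window
  out <- m[hit, c("protein", "start", "prediction", "site", "p1prime",
                  "deviation"), drop = FALSE]
  out <- out[order(out$protein, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster ragged neo-terminus starts
#'
#' Transitive single-linkage: consecutive starts (per protein) closer
#' than or equal to \code{gap} residues join one cluster. Used to merge
#' aminopeptidase-trimmed variants of one primary cleavage event.
#'
#' @param starts Sorted or unsorted integer vector of start positions.
#' @param gap Maximum within-cluster spacing (default 5 residues).
#' @return Integer vector of cluster ids parallel to \code{starts}.
#' @export
clusterStarts <- function(starts, gap = 5L) {
  o <- order(starts)
  s <- starts[o]
  cl <- cumsum(c(1L, diff(s) > gap))
  out <- integer(length(starts))
  out[o] <- cl
  out
}

#' Select representative (primary) cleavage N-termini
#'
#' Restricts matched neo-N-termini to proteins with the required
#' consensus subcellular localization, clusters starts within
#' \code{gap} residues per protein, and selects the most upstream
#' (smallest) start of each cluster as the representative, presumed
#' primary, cleavage product; later starts are taken as
#' aminopeptidase-trimmed variants.
#'
#' @param matches \code{data.frame} from \code{\link{matchCleavage}}.
#' @param localization \code{data.frame} from
#'   \code{\link{readLocalization}}; proteins absent from it are
#'   excluded and reported in the \code{"excluded"} attribute.
#' @param compartment Required consensus compartment (default
#'   \code{"chloroplast"}).
#' @param gap Cluster spacing (default 5 residues).
#' @return \code{matches} restricted to the compartment, with added
#'   columns \code{cluster} and \code{isRepresentative}.
#' @export
selectRepresentative <- function(matches, localization,
                                 compartment = "chloroplast", gap = 5L) {
  loc <- localization
  known <- matches$protein %in% loc$protein
  excluded <- unique(matches$protein[!known])
  m <- matches[known, , drop = FALSE]
  comp <- loc$compartment[match(m$protein, loc$protein)]
  m <- m[comp == compartment, , drop = FALSE]
  if (nrow(m)) {
    m$cluster <- NA_integer_
    m$isRepresentative <- FALSE
    for (p in unique(m$protein)) {
      idx <- which(m$protein == p)
      cl <- clusterStarts(m$start[idx], gap = gap)
      m$cluster[idx] <- cl
      for (c0 in unique(cl)) {
        sub <- idx[cl == c0]
        m$isRepresentative[sub[which.min(m$start[sub])]] <- TRUE
      }
    }
  } else {
    m$cluster <- integer(0)
    m$isRepresentative <- logical(0)
  }
  rownames(m) <- NULL
  attr(m, "excluded") <- excluded
  m
}

#' Amino-acid frequency matrix around cleavage sites
#'
#' Builds a position frequency matrix over the ten positions P5..P1 and
#' P1'..P5' flanking each representative cleavage site (P1' = the
#' N-terminus start). Sites closer than five residues to the protein
#' start are padded with the gap symbol \code{"-"}. With a background
#' residue-frequency vector, a log2 enrichment matrix is attached.
#'
#' @param sites \code{data.frame} with columns \code{protein} and
#'   \code{start} (the P1' position).
#' @param proteins Named character vector (or \code{AAStringSet}) of
#'   protein sequences.
#' @param background Optional named numeric vector of residue
#'   frequencies.
#' @return A list with \code{freq} (21 x 10 matrix, columns P5..P5',
#'   each column summing to 1), \code{nSites}, and optionally
#'   \code{enrichment}.
#' @export
motifMatrix <- function(sites, proteins, background = NULL) {
  if (methods::is(proteins, "AAStringSet"))
    proteins <- as.character(proteins)
  positions <- c(paste0("P", 5:1), paste0("P", 1:5, "p"))
  alphabet <- c(AA20, "-")
  counts <- matrix(0L, nrow = length(alphabet), ncol = 10L,
                   dimnames = list(alphabet, positions))
  n <- 0L
  for (i in seq_len(nrow(sites))) {
    seq <- proteins[[sites$protein[i]]]
    if (is.null(seq) || is.na(seq)) next
    p1p <- sites$start[i]
    win <- (p1p - 5L):(p1p + 4L)
    res <- ifelse(win >= 1L & win <= nchar(seq),
                  substring(seq, win, win), "-")
    res[!res %in% alphabet] <- "-"
    for (j in seq_along(res))
      counts[res[j], j] <- counts[res[j], j] + 1L
    n <- n + 1L
  }
  freq <- if (n > 0L) counts / n else counts
  out <- list(freq = freq, nSites = n)
  if (!is.null(background) && n > 0L) {
    bg <- background[rownames(freq)]
    bg[is.na(bg) | bg <= 0] <- NA
    out$enrichment <- log2(sweep(freq, 1L, bg, "/"))
  }
  out
}

#' Write a motif frequency matrix as TSV
#'
#' @param motif List from \code{\link{motifMatrix}}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeMotifMatrix <- function(motif, path) {
  df <- data.frame(residue = rownames(motif$freq), motif$freq,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
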
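#' Degree of in vivo N-terminal acetylation
#'
#' In vivo acetylated (light acetyl) and in vivo free (in vitro heavy
#' 13C2D3-acetylated) precursor pairs differ by 5 Da; the degree of in
#' vivo NTA is the light intensity as a percentage of the summed pair,
#' \eqn{100 \times L / (L + H)}.
#'
#' @param light,heavy Non-negative precursor intensities.
#' @return Numeric percent in \code{[0, 100]}; \code{NA} when both
#'   intensities are zero (the record should be skipped and reported).
#' @examples
#' ntaDegree(800, 200)  # 80
#' @export
ntaDegree <- function(light, heavy) {
  stopifnot(all(light >= 0), all(heavy >= 0))
  tot <- light + heavy
  ifelse(tot > 0, 100 * light / tot, NA_real_)
}

#' Aggregate precursor pairs to per-N-terminus NTA degrees
#'
#' Intensities are summed across contributing pairs before taking the
#' ratio (default), or per-pair degrees are averaged
#' (\code{method = "mean"}). Per-pair degrees and their spread are
#' reported alongside.
#'
#' @param pairs \code{data.frame} with columns \code{protein},
#'   \code{start}, \code{intensity_light}, \code{intensity_heavy}.
#' @param method \code{"sum"} (default) or \code{"mean"}.
#' @return \code{data.frame} with \code{protein}, \code{start},
#'   \code{light}, \code{heavy}, \code{degree}, \code{nPairs},
#'   \code{pairSd}; pairs with both intensities zero are skipped and
#'   counted in the \code{"nSkipped"} attribute.
#' @export
aggregateDegrees <- function(pairs, method = c("sum", "mean")) {
  method <- match.arg(method)
  need <- c("protein", "start", "intensity_light", "intensity_heavy")
  stopifnot(all(need %in% names(pairs)))
  zero <- pairs$intensity_light + pairs$intensity_heavy <= 0
  skipped <- sum(zero)
  pairs <- pairs[!zero, , drop = FALSE]
  if (!nrow(pairs)) {
    out <- data.frame(protein = character(), start = integer(),
                      light = numeric(), heavy = numeric(),
                      degree = numeric(), nPairs = integer(),
                      pairSd = numeric(), stringsAsFactors = FALSE)
    attr(out, "nSkipped") <- skipped
    return(out)
  }
  key <- paste(pairs$protein, pairs$start, sep = "\r")
  groups <- split(seq_len(nrow(pairs)), key)
  rows <- lapply(groups, function(idx) {
    g <- pairs[idx, , drop = FALSE]
    L <- sum(g$intensity_light); H <- sum(g$intensity_heavy)
    per <- ntaDegree(g$intensity_light, g$intensity_heavy)
    deg <- if (method == "sum") ntaDegree(L, H) else mean(per)
    data.frame(protein = g$protein[1], start = g$start[1], light = L,
               heavy = H, degree = deg, nPairs = nrow(g),
               pairSd = if (nrow(g) > 1L) sd(per) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nSkipped") <- skipped
  out
}

#' Summarize NTA degrees by N-terminus class
#'
#' Groups degrees by origin and NAT class (or mature first residue) and
#' reports n, mean, median and quartiles; groups with fewer than
#' \code{minN} observations are suppressed.
#'
#' @param degrees \code{data.frame} from \code{\link{aggregateDegrees}}.
#' @param records Classified N-termini from \code{\link{classifyOrigin}}
#'   (matched on \code{protein} + \code{start}).
#' @param by \code{"natClass"} (default) or \code{"residue"} (mature
#'   N-terminal residue).
#' @param minN Minimum observations per group (default 5).
#' @return \code{data.frame} with \code{origin}, \code{group}, \code{n},
#'   \code{mean}, \code{median}, \code{q1}, \code{q3}.
#' @export
classSummary <- function(degrees, records, by = c("natClass", "residue"),
                         minN = 5L) {
  by <- match.arg(by)
  m <- merge(degrees, records, by = c("protein", "start"))
  if (!nrow(m)) {
    return(data.frame(origin = character(), group = character(),
                      n = integer(), mean = numeric(), median = numeric(),
                      q1 = numeric(), q3 = numeric(), stringsAsFactors = FALSE))
  }
  m$group <- if (by == "natClass") m$natClass else {
    first <- substr(m$peptide, 1L, 1L)
    ifelse(first == "M", substr(m$peptide, 1L, 2L), first)
  }
  key <- paste(m$origin, m$group, sep = "\r")
  groups <- split(seq_len(nrow(m)), key)
  rows <- lapply(groups, function(idx) {
    d <- m$degree[idx]
    data.frame(origin = m$origin[idx[1]], group = m$group[idx[1]],
               n = length(d), mean = mean(d), median = median(d),
               q1 = unname(quantile(d, 0.25)), q3 = unname(quantile(d, 0.75)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n >= minN, , drop = FALSE]
  out <- out[order(out$origin, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
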
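## Local-alignment specificity screening.
##
## The screen mirrors a default-parameter BLASTN search: raw Smith-Waterman
## score with match +2, mismatch -3, gap open 5, gap extend 2 (a gap of
## length L costs 5 + 2L), best over both strands, clamped at 0. Correctness
## is defined by the full Smith-Waterman recurrence; for genome-scale
## subjects an 11-mer seed-and-extend accelerator restricts the exact DP to
## windows around exact seed hits.

.SCORING <- list(match = 2, mismatch = -3, gapOpening = 5, gapExtension = 2)

.subMatrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      letters <- c("A", "C", "G", "T", "N")
      m <- matrix(.SCORING$mismatch, 5, 5, dimnames = list(letters, letters))
      diag(m) <- .SCORING$match
      m["N", ] <- m[, "N"] <- .SCORING$mismatch  # N never matches, incl. N-N
      mat <<- m
    }
    mat
  }
})

.asDNASet <- function(subject) {
  if (is(subject, "Genome")) {
    if (!hasSequence(subject))
      stop("subject genome is coordinate-only; sequence required")
    subject@sequences
  } else if (is(subject, "DNAStringSet")) subject
  else if (is(subject, "DNAString")) Biostrings::DNAStringSet(list(subject))
  else Biostrings::DNAStringSet(as.character(subject))
}

.swScore <- function(query, subjectSeq) {
  pa <- Biostrings::pairwiseAlignment(
    query, subjectSeq, type = "local",
    substitutionMatrix = .subMatrix(),
    gapOpening = .SCORING$gapOpening, gapExtension = .SCORING$gapExtension,
    scoreOnly = TRUE)
  max(0, pa)
}

## Exact seed k-mers of a query: PDict plus, per k-mer, the range of query
## offsets where it occurs (for tight window placement). NULL when unusable.
.seedDict <- function(query, seedLength) {
  q <- as.character(query)
  m <- nchar(q)
  if (m < seedLength) return(NULL)
  kmers <- substring(q, 1:(m - seedLength + 1), seedLength:m)
  ok <- !grepl("N", kmers, fixed = TRUE)
  if (!any(ok)) return(NULL)
  byKmer <- split(which(ok), kmers[ok])
  list(pdict = Biostrings::PDict(Biostrings::DNAStringSet(names(byKmer))),
       qmin = vapply(byKmer, min, numeric(1)),
       qmax = vapply(byKmer, max, numeric(1)),
       m = m)
}

## Seed windows: plus-strand intervals of `subjectSeq` containing an exact
## seed of the query, padded so any alignment through the seed fits inside.
.seedWindows <- function(query, subjectSeq, seedLength, pad,
                         dict = .seedDict(query, seedLength)) {
  m <- nchar(as.character(query))
  if (m < seedLength) return(IRanges::IRanges(1, length(subjectSeq)))
  if (is.null(dict)) return(IRanges::IRanges())
  hits <- Biostrings::startIndex(
    Biostrings::matchPDict(dict$pdict, subjectSeq))
  nhit <- lengths(hits)
  if (sum(nhit) == 0L) return(IRanges::IRanges())
  st <- unlist(hits, use.names = FALSE)
  qmin <- rep(dict$qmin, nhit)
  qmax <- rep(dict$qmax, nhit)
  iv <- IRanges::IRanges(
    pmax(1L, floor(st - (qmax - 1) - pad)),
    pmin(length(subjectSeq),
         ceiling(st + seedLength - 1L + (m - qmin) + pad)))
  IRanges::reduce(iv)
}

## Seeded max-score path: one batched Smith-Waterman call per strand over
## all seed windows of all subject sequences.
.seededMaxScore <- function(q, subj, seedLength) {
  best <- 0
  for (qq in list(q, Biostrings::reverseComplement(q))) {
    dict <- .seedDict(qq, seedLength)
    wins <- list()
    for (i in seq_along(subj)) {
      s <- subj[[i]]
      if (length(qq) < seedLength) {  # short query: score everything
        wins[[length(wins) + 1L]] <- Biostrings::DNAStringSet(list(s))
        next
      }
      win <- .seedWindows(qq, s, seedLength, pad = 50L, dict = dict)
      if (length(win))
        wins[[length(wins) + 1L]] <- Biostrings::extractAt(s, win)
    }
    if (length(wins) == 0L) next
    winSet <- do.call(c, wins)
    sc <- Biostrings::pairwiseAlignment(
      winSet, qq, type = "local", substitutionMatrix = .subMatrix(),
      gapOpening = .SCORING$gapOpening, gapExtension = .SCORING$gapExtension,
      scoreOnly = TRUE)
    best <- max(best, sc)
  }
  max(0, best)
}

#' Maximum local-alignment raw score of a query against a genome
#'
#' Best Smith-Waterman raw score of \code{query} (either strand) against any
#' location of \code{subject}, under the blastn-like scheme match +2,
#' mismatch -3, gap open 5, gap extend 2. Never negative. \code{method
#' "full"} runs the exact DP over everything; \code{"seeded"} restricts the
#' DP to windows around exact 11-mer seed hits (alignments whose every seed
#' is shorter than 11 bases are below the detectability of the screen and
#' score 0); \code{"auto"} picks \code{"full"} for small subjects.
#'
#' @param query query sequence (character or DNAString).
#' @param subject a [Genome-class], DNAStringSet, DNAString or character.
#' @param method \code{"auto"}, \code{"full"} or \code{"seeded"}.
#' @param seedLength exact seed length for the accelerated path.
#' @return integer-valued numeric score (>= 0).
#' @examples
#' maxLocalAlignmentScore("ACGTACGTAC", "TTTACGTACGTACTTT")  # 20
#' @export
maxLocalAlignmentScore <- function(query, subject,
                                   method = c("auto", "full", "seeded"),
                                   seedLength = 11) {
  method <- match.arg(method)
  subj <- .asDNASet(subject)
  if (length(subj) == 0L) return(0)
  q <- if (is(query, "DNAString")) query else Biostrings::DNAString(as.character(query))
  if (length(q) == 0L) stop("query must be non-empty")
  qs <- list(q, Biostrings::reverseComplement(q))
  if (method == "auto") {
    cells <- as.numeric(length(q)) * sum(as.numeric(Biostrings::width(subj)))
    method <- if (cells <= 2e7) "full" else "seeded"
  }
  if (method == "seeded") return(.seededMaxScore(q, subj, seedLength))
  best <- 0
  for (i in seq_along(subj)) {
    s <- subj[[i]]
    for (qq in qs) best <- max(best, .swScore(qq, s))
  }
  best
}

#' Species-specificity of a candidate region
#'
#' A region is species-specific when no local alignment against the
#' recipient genome scores more than \code{cutoff} (a hit scoring exactly
#' \code{cutoff} is still tolerated, mirroring a "no hits with a score of
#' more than 50" rule).
#'
#' @param regionSeq candidate region sequence.
#' @param recipient recipient [Genome-class] (or sequences).
#' @param cutoff raw-score cutoff (> 0), default 50.
#' @inheritParams maxLocalAlignmentScore
#' @return TRUE iff the best score is <= cutoff.
#' @export
regionIsSpeciesSpecific <- function(regionSeq, recipient, cutoff = 50,
                                    method = c("auto", "full", "seeded")) {
  stopifnot(cutoff > 0)
  maxLocalAlignmentScore(regionSeq, recipient, method = match.arg(method)) <= cutoff
}

.revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.suffixOccurs <- function(suffix, subjSet) {
  pat <- Biostrings::DNAString(suffix)
  if (sum(Biostrings::vcountPattern(pat, subjSet)) > 0) return(TRUE)
  sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), subjSet)) > 0
}

#' Longest 3'-anchored exact match of a primer in a genome
#'
#' Length of the longest suffix of the primer that occurs exactly (either
#' strand) in the subject. The default \code{"exhaustive"} method searches
#' the whole subject; \code{"seeded"} restricts the search to windows of
#' local similarity (exact 11-mer seed hits of the primer), which is how a
#' BLAST-style alignment report is inspected at the 3' ends - at genome
#' scale a short suffix occurs somewhere by chance with near certainty, so
#' the exhaustive search is only meaningful against small or pre-restricted
#' subjects.
#'
#' @param primer primer sequence (5'->3').
#' @param subject a [Genome-class], DNAStringSet, DNAString or character.
#' @param method \code{"exhaustive"} or \code{"seeded"}.
#' @param seedLength seed length for the seeded method.
#' @return integer in \code{0..nchar(primer)}.
#' @export
longestThreePrimeMatch <- function(primer, subject,
                                   method = c("exhaustive", "seeded"),
                                   seedLength = 11) {
  method <- match.arg(method)
  subj <- .asDNASet(subject)
  p <- as.character(primer)
  m <- nchar(p)
  if (m == 0L) stop("primer must be non-empty")
  if (length(subj) == 0L || sum(Biostrings::width(subj)) == 0L) return(0L)
  if (method == "seeded") {
    q <- Biostrings::DNAString(p)
    wins <- list()
    for (qq in list(q, Biostrings::reverseComplement(q))) {
      dict <- .seedDict(qq, seedLength)
      for (i in seq_along(subj)) {
        win <- .seedWindows(qq, subj[[i]], seedLength, pad = 10L, dict = dict)
        if (length(win))
          wins[[length(wins) + 1L]] <- Biostrings::extractAt(subj[[i]], win)
      }
    }
    if (length(wins) == 0L) return(0L)
    subj <- do.call(c, wins)
  }
  ## binary search: suffix occurrence is monotone in suffix length
  lo <- 0L; hi <- m
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (.suffixOccurs(substr(p, m - mid + 1L, m), subj)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' 3'-end specificity filter for a primer
#'
#' A primer passes when its longest 3'-anchored exact match in the recipient
#' is at most \code{cutoffBp} bases (more than eight matching bases at the
#' 3' end is rejected under the default).
#'
#' @inheritParams longestThreePrimeMatch
#' @param recipient recipient genome or sequences.
#' @param cutoffBp maximum tolerated 3'-anchored match (default 8).
#' @return TRUE iff the primer passes.
#' @export
primerPassesThreePrimeFilter <- function(primer, recipient, cutoffBp = 8,
                                         method = c("exhaustive", "seeded")) {
  stopifnot(cutoffBp >= 0)
  longestThreePrimeMatch(primer, recipient, method = match.arg(method)) <= cutoffBp
}
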
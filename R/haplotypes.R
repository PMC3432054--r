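## Junction/segment representation of a haplotype: a list with numeric
## `ends` (segment end coordinates, 0-based half-open, last element = the
## chromosome length) and character `origins` ("donor"/"recipient"), held in
## canonical merged form (adjacent segments differ in origin, no zero-width
## segments). Kept as a bare list for speed inside the simulator; exposed
## through the helpers below.

#' Build a single-origin haplotype
#'
#' @param length chromosome length in bp.
#' @param origin \code{"donor"} or \code{"recipient"}.
#' @return a haplotype (see [haplotypeSegments()]).
#' @export
newHaplotype <- function(length, origin = c("recipient", "donor")) {
  origin <- match.arg(origin)
  list(ends = as.numeric(length), origins = origin)
}

#' Haplotype from explicit segments
#'
#' @param starts,ends,origins parallel vectors of 0-based half-open segments
#'   tiling the chromosome.
#' @return a canonical haplotype.
#' @export
haplotypeFromSegments <- function(starts, ends, origins) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; origins <- origins[o]
  if (starts[1] != 0 || any(starts[-1] != ends[-length(ends)]))
    stop("segments must tile the chromosome without gaps or overlaps")
  if (any(ends <= starts)) stop("segments must have start < end")
  .canonicalHap(ends, origins)
}

.canonicalHap <- function(ends, origins) {
  keep <- c(diff(ends) > 0, TRUE)  # drop zero-width
  ends <- ends[keep]; origins <- origins[keep]
  if (length(ends) > 1L) {
    same <- origins[-length(origins)] == origins[-1]
    if (any(same)) {
      keep <- c(!same, TRUE)
      ends <- ends[keep]; origins <- origins[keep]
    }
  }
  list(ends = ends, origins = origins)
}

#' Segment view of a haplotype
#'
#' @param hap a haplotype.
#' @return data.frame with \code{start}, \code{end} (0-based half-open) and
#'   \code{origin}.
#' @export
haplotypeSegments <- function(hap) {
  data.frame(start = c(0, hap$ends[-length(hap$ends)]), end = hap$ends,
             origin = hap$origins)
}

#' Ancestry at a position
#'
#' @param hap a haplotype.
#' @param pos 0-based position(s).
#' @return character vector of origins.
#' @export
originAt <- function(hap, pos) {
  hap$origins[findInterval(pos, hap$ends, left.open = FALSE) + 1L]
}

## Donor bp carried by a haplotype.
.donorBp <- function(hap) {
  w <- diff(c(0, hap$ends))
  sum(w[hap$origins == "donor"])
}

## Bounds (start, end) of the segment containing `pos`, or NULL if the
## origin there is not `origin`.
.segmentAt <- function(hap, pos, origin = "donor") {
  i <- findInterval(pos, hap$ends, left.open = FALSE) + 1L
  if (hap$origins[i] != origin) return(NULL)
  c(if (i == 1L) 0 else hap$ends[i - 1L], hap$ends[i])
}

## Recombine two haplotypes at sorted physical cut positions; the gamete
## starts on `startWith` (1 = A, 2 = B) and switches source at each cut.
.recombineHaplotypes <- function(hapA, hapB, cuts, startWith = 1L) {
  if (length(cuts) == 0L)
    return(if (startWith == 1L) hapA else hapB)
  L <- hapA$ends[length(hapA$ends)]
  cuts <- cuts[cuts > 0 & cuts < L]
  if (length(cuts) == 0L)
    return(if (startWith == 1L) hapA else hapB)
  bounds <- c(0, cuts, L)
  ends <- numeric(0); origins <- character(0)
  src <- startWith
  haps <- list(hapA, hapB)
  for (j in seq_len(length(bounds) - 1L)) {
    lo <- bounds[j]; hi <- bounds[j + 1L]
    if (hi > lo) {
      h <- haps[[src]]
      i1 <- findInterval(lo, h$ends, left.open = FALSE) + 1L
      i2 <- findInterval(hi, h$ends, left.open = TRUE) + 1L
      e <- h$ends[i1:i2]
      e[length(e)] <- hi
      ends <- c(ends, e)
      origins <- c(origins, h$origins[i1:i2])
    }
    src <- 3L - src
  }
  .canonicalHap(ends, origins)
}

## Haplotype tiling sanity check (used by tests and validity-minded callers).
.hapIsValid <- function(hap, L) {
  length(hap$ends) == length(hap$origins) &&
    all(diff(c(0, hap$ends)) > 0) &&
    isTRUE(all.equal(hap$ends[length(hap$ends)], L)) &&
    (length(hap$origins) < 2L ||
       all(hap$origins[-1] != hap$origins[-length(hap$origins)]))
}
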
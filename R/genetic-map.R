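#' Construct a GeneticMap from anchor points
#'
#' @param anchors data.frame with columns \code{chrom}, \code{physical_bp},
#'   \code{genetic_cM}.
#' @return a [GeneticMap-class].
#' @export
GeneticMap <- function(anchors) {
  anchors <- anchors[order(anchors$chrom, anchors$physical_bp), , drop = FALSE]
  rownames(anchors) <- NULL
  cache <- new.env(parent = emptyenv())
  for (ch in unique(anchors$chrom)) {
    s <- anchors[anchors$chrom == ch, , drop = FALSE]
    assign(ch, list(p = s$physical_bp, g = s$genetic_cM), envir = cache)
  }
  new("GeneticMap", anchors = anchors, cache = cache)
}

#' @export
setMethod("show", "GeneticMap", function(object) {
  a <- object@anchors
  for (ch in unique(a$chrom)) {
    s <- a[a$chrom == ch, ]
    cat(sprintf("GeneticMap %s: %.2f Mb / %.1f cM (%d anchors)\n",
                ch, max(s$physical_bp) / 1e6, max(s$genetic_cM), nrow(s)))
  }
})

#' Arm-weighted genetic map
#'
#' Builds the recombination landscape typical of Caenorhabditis chromosomes:
#' the physical arms (outer \code{armFraction} of each chromosome on both
#' sides) carry most of the genetic length, the centre relatively little.
#' With the defaults each chromosome is 50 cM: 20 cM on each arm covering a
#' quarter of the physical length, 10 cM across the central half.
#'
#' @param lengths named numeric vector of chromosome lengths in bp (or a
#'   [Genome-class]).
#' @param armFraction physical fraction of the chromosome per arm.
#' @param armCM genetic lengths in cM of \code{c(left arm, centre, right arm)}.
#' @return a [GeneticMap-class] with four anchors per chromosome.
#' @examples
#' m <- armWeightedMap(c(I = 15e6))
#' physicalToGenetic(m, "I", 1.875e6)  # mid left arm: 10 cM
#' @export
armWeightedMap <- function(lengths, armFraction = 0.25, armCM = c(20, 10, 20)) {
  if (is(lengths, "Genome")) lengths <- chromLengths(lengths)
  stopifnot(length(armCM) == 3L, armFraction > 0, armFraction < 0.5)
  anchors <- do.call(rbind, lapply(names(lengths), function(ch) {
    L <- lengths[[ch]]
    data.frame(chrom = ch,
               physical_bp = c(0, armFraction * L, (1 - armFraction) * L, L),
               genetic_cM = cumsum(c(0, armCM)))
  }))
  GeneticMap(anchors)
}

#' Uniform genetic map
#'
#' @param lengths named chromosome lengths in bp (or a [Genome-class]).
#' @param cM genetic length per chromosome in cM.
#' @return a [GeneticMap-class].
#' @export
uniformMap <- function(lengths, cM = 50) {
  if (is(lengths, "Genome")) lengths <- chromLengths(lengths)
  anchors <- do.call(rbind, lapply(names(lengths), function(ch) {
    data.frame(chrom = ch, physical_bp = c(0, lengths[[ch]]),
               genetic_cM = c(0, cM))
  }))
  GeneticMap(anchors)
}

.mapAnchors <- function(map, chrom) {
  s <- get0(chrom, envir = map@cache, inherits = FALSE)
  if (is.null(s)) stop("no genetic map for chromosome '", chrom, "'")
  s
}

## linear interpolation over sorted breakpoints (both vectors increasing)
.interp <- function(x, y, xout) {
  i <- findInterval(xout, x, all.inside = TRUE)
  y[i] + (xout - x[i]) * (y[i + 1L] - y[i]) / (x[i + 1L] - x[i])
}

#' Convert between physical and genetic coordinates
#'
#' Piecewise-linear interpolation between the map's anchor points;
#' `geneticToPhysical()` is the exact inverse away from anchors.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome name.
#' @param pos physical position(s) in bp (vectorized).
#' @return numeric vector of genetic positions in cM.
#' @examples
#' m <- GeneticMap(data.frame(chrom = "I", physical_bp = c(0, 15e6),
#'                            genetic_cM = c(0, 50)))
#' physicalToGenetic(m, "I", 7.5e6)  # 25
#' @export
physicalToGenetic <- function(map, chrom, pos) {
  s <- .mapAnchors(map, chrom)
  if (any(pos < 0 | pos > s$p[length(s$p)]))
    stop("position out of range [0, ", s$p[length(s$p)], "] on '", chrom, "'")
  .interp(s$p, s$g, pos)
}

#' @rdname physicalToGenetic
#' @param cM genetic position(s) in cM (vectorized).
#' @return for `geneticToPhysical()`, numeric physical positions in bp.
#' @export
geneticToPhysical <- function(map, chrom, cM) {
  s <- .mapAnchors(map, chrom)
  if (any(cM < 0 | cM > s$g[length(s$g)]))
    stop("genetic position out of range [0, ", s$g[length(s$g)], "] on '",
         chrom, "'")
  .interp(s$g, s$p, cM)
}

#' @rdname physicalToGenetic
#' @return for `mapLengthCM()`, the genetic length of the chromosome in cM.
#' @export
mapLengthCM <- function(map, chrom) {
  s <- .mapAnchors(map, chrom)
  s$g[length(s$g)]
}

#' @rdname physicalToGenetic
#' @return for `mapLengthBp()`, the physical length covered by the map in bp.
#' @export
mapLengthBp <- function(map, chrom) {
  s <- .mapAnchors(map, chrom)
  s$p[length(s$p)]
}
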
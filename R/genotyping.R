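#' Coordinate-mode in-silico PCR on an individual
#'
#' A pair amplifies when at least one haplotype of its chromosome carries a
#' single donor segment covering both primer binding intervals -
#' heterozygous templates suffice (dominant presence/absence readout), but a
#' donor segment ending between the primers, or primers on different
#' haplotypes, cannot yield a contiguous template.
#'
#' @param ind an [Individual-class].
#' @param pair one panel row (or a list with \code{chrom},
#'   \code{left_start}, \code{right_end}).
#' @return TRUE iff a product is expected.
#' @export
insilicoPcrCoordinate <- function(ind, pair) {
  hs <- ind@haplotypes[[pair$chrom]]
  if (is.null(hs))
    stop("individual has no chromosome '", pair$chrom, "'")
  for (h in hs) {
    seg <- .segmentAt(h, pair$left_start, "donor")
    if (!is.null(seg) && seg[2] >= pair$right_end) return(TRUE)
  }
  FALSE
}

## Plus-strand binding sites of `primer` used as a forward primer (site
## read 5'->3' along plus strand: 3'-terminal `core` bases exact, at most
## `maxMM` mismatches in the rest) and as a reverse primer (site is the
## reverse complement). Returns list of IRanges per subject sequence.
.bindingSites <- function(primer, subj, core, maxMM) {
  p <- Biostrings::DNAString(primer)
  m <- length(p)
  coreLen <- min(core, m)
  fwd <- Biostrings::vmatchPattern(p, subj, max.mismatch = maxMM)
  rcp <- Biostrings::reverseComplement(p)
  rev <- Biostrings::vmatchPattern(rcp, subj, max.mismatch = maxMM)
  checkCore <- function(ir, s, pat, atStart) {
    if (length(ir) == 0L) return(ir)
    keep <- logical(length(ir))
    for (j in seq_along(ir)) {
      st <- IRanges::start(ir)[j]; en <- IRanges::end(ir)[j]
      if (st < 1 || en > length(s)) { keep[j] <- FALSE; next }
      hitSeq <- Biostrings::subseq(s, st, en)
      keep[j] <- if (atStart)
        as.character(Biostrings::subseq(hitSeq, 1, coreLen)) ==
          as.character(Biostrings::subseq(pat, 1, coreLen))
      else
        as.character(Biostrings::subseq(hitSeq, length(pat) - coreLen + 1, length(pat))) ==
          as.character(Biostrings::subseq(pat, length(pat) - coreLen + 1, length(pat)))
    }
    ir[keep]
  }
  lapply(seq_along(subj), function(i) {
    s <- subj[[i]]
    ## forward: 3' end of the primer is at the match end
    f <- checkCore(fwd[[i]], s, p, atStart = FALSE)
    ## reverse: primer 3' end maps to the match start on the plus strand
    r <- checkCore(rev[[i]], s, rcp, atStart = TRUE)
    list(fwd = f, rev = r)
  })
}

#' Sequence-mode in-silico PCR on a genome
#'
#' A primer binds where its 3'-terminal core (default 15 nt) matches the
#' template exactly and the remainder of the primer has at most 2
#' mismatches; a product is called when a facing forward/reverse pair of
#' binding sites (either pair orientation) lies within
#' \code{maxProductBp}. This binding rule is the single point where
#' sequence mode can diverge from coordinate mode, so it is centralized and
#' configurable.
#'
#' @param template a [Genome-class] with sequence, or a DNAStringSet.
#' @param pair one panel row with \code{left_seq} and \code{right_seq}.
#' @param maxProductBp largest product considered amplifiable.
#' @param coreBp exact-match 3' core length.
#' @param maxMismatch mismatches tolerated outside the core.
#' @return list with \code{amplified} and \code{products} (data.frame:
#'   seqname, start, end, size; 0-based half-open).
#' @export
insilicoPcrSequence <- function(template, pair, maxProductBp = 2000,
                                coreBp = 15, maxMismatch = 2) {
  subj <- .asDNASet(template)
  if (is.na(pair$left_seq) || is.na(pair$right_seq))
    stop("pair carries no primer sequences; use insilicoPcrCoordinate()")
  sitesL <- .bindingSites(pair$left_seq, subj, coreBp, maxMismatch)
  sitesR <- .bindingSites(pair$right_seq, subj, coreBp, maxMismatch)
  prods <- list()
  for (i in seq_along(subj)) {
    for (ori in 1:2) {
      f <- if (ori == 1) sitesL[[i]]$fwd else sitesR[[i]]$fwd
      r <- if (ori == 1) sitesR[[i]]$rev else sitesL[[i]]$rev
      if (length(f) == 0L || length(r) == 0L) next
      for (a in IRanges::start(f)) {
        ends <- IRanges::end(r)[IRanges::start(r) > a &
                                  IRanges::end(r) - a + 1 <= maxProductBp]
        for (b in ends)
          prods[[length(prods) + 1L]] <- data.frame(
            seqname = names(subj)[i] %||% as.character(i),
            start = a - 1, end = b, size = b - a + 1)
      }
    }
  }
  products <- if (length(prods)) unique(do.call(rbind, prods)) else
    data.frame(seqname = character(0), start = numeric(0), end = numeric(0),
               size = numeric(0))
  list(amplified = nrow(products) > 0, products = products)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render an individual's chromosomes to sequence
#'
#' Stitches donor and recipient sequence along each haplotype's ancestry
#' segments. Requires the two genomes to share per-chromosome coordinates
#' (equal lengths), i.e. divergence without indels.
#'
#' @param ind an [Individual-class].
#' @param donor,recipient [Genome-class] objects with sequence.
#' @return a DNAStringSet with one entry per haplotype, named
#'   \code{<chrom>.h1}/\code{<chrom>.h2}.
#' @export
renderIndividualGenome <- function(ind, donor, recipient) {
  out <- list()
  for (ch in names(ind@haplotypes)) {
    Ld <- chromLengths(donor)[[ch]]
    Lr <- chromLengths(recipient)[[ch]]
    if (is.na(Ld) || Ld != Lr)
      stop("rendering requires equal donor/recipient lengths on ", ch,
           " (no-indel divergence)")
    dch <- donor@sequences[[ch]]
    rch <- recipient@sequences[[ch]]
    for (k in seq_along(ind@haplotypes[[ch]])) {
      h <- ind@haplotypes[[ch]][[k]]
      segs <- haplotypeSegments(h)
      pieces <- lapply(seq_len(nrow(segs)), function(j) {
        src <- if (segs$origin[j] == "donor") dch else rch
        Biostrings::subseq(src, segs$start[j] + 1, segs$end[j])
      })
      stitched <- if (length(pieces) == 1L) pieces[[1]]
                  else do.call(Biostrings::xscat, pieces)
      out[[sprintf("%s.h%d", ch, k)]] <- stitched
    }
  }
  Biostrings::DNAStringSet(out)
}

## Stage-1 representative: the median-coordinate pair of each arm group.
.armRepresentatives <- function(rows) {
  picks <- integer(0)
  for (a in c("left", "middle", "right")) {
    g <- which(rows$arm == a)
    if (length(g) == 0L) next
    g <- g[order(rows$mid[g])]
    picks <- c(picks, g[ceiling(length(g) / 2)])
  }
  picks
}

#' Hierarchical two-stage genotyping
#'
#' Stage 1 runs one left-arm, one middle and one right-arm pair per autosome
#' (15 reactions on a five-autosome karyotype). When exactly one chromosome
#' is positive, stage 2 runs its remaining pairs, for a total of
#' 15 + (n_chrom - 3) reactions. When the marker is already known to be
#' X-linked only the full X panel is run. Zero stage-1 positives trigger an
#' X fallback; positives on two or more chromosomes are surfaced as a
#' multi-chromosome flag (an anomaly worth reporting, not an error).
#'
#' @param ind an [Individual-class].
#' @param panel panel data.frame with arm labels; pairs with status
#'   \code{"discarded"} are ignored.
#' @param xLinkedKnown run only the X panel.
#' @param xChrom name of the X chromosome in the panel.
#' @return list with \code{assignment} (chromosome name(s) or NA),
#'   \code{pattern} (data.frame: primer_id, chrom, pos, call - the
#'   genotype pattern of the assigned chromosome(s)), \code{reactionsUsed}
#'   and \code{multiChromosome}.
#' @export
hierarchicalGenotype <- function(ind, panel, xLinkedKnown = FALSE,
                                 xChrom = "X") {
  panel <- panel[panel$status != "discarded", , drop = FALSE]
  panel$mid <- (panel$left_start + panel$right_end) / 2
  callRows <- function(rows) {
    vapply(seq_len(nrow(rows)), function(i)
      insilicoPcrCoordinate(ind, rows[i, ]), logical(1))
  }
  asPattern <- function(rows, calls) {
    out <- data.frame(primer_id = rows$id, chrom = rows$chrom,
                      pos = rows$mid, call = calls,
                      stringsAsFactors = FALSE)
    out[order(out$chrom, out$pos), ]
  }
  xRows <- panel[panel$chrom == xChrom, , drop = FALSE]
  if (xLinkedKnown) {
    calls <- callRows(xRows)
    return(list(assignment = if (any(calls)) xChrom else NA_character_,
                pattern = asPattern(xRows, calls),
                reactionsUsed = nrow(xRows), multiChromosome = FALSE))
  }
  reactions <- 0L
  stage1 <- list(); stage1Calls <- list()
  for (ch in setdiff(unique(panel$chrom), xChrom)) {
    rows <- panel[panel$chrom == ch, , drop = FALSE]
    reps <- rows[.armRepresentatives(rows), , drop = FALSE]
    stage1[[ch]] <- reps
    stage1Calls[[ch]] <- callRows(reps)
    reactions <- reactions + nrow(reps)
  }
  posChrom <- names(stage1Calls)[vapply(stage1Calls, any, logical(1))]
  if (length(posChrom) == 0L) {
    ## X fallback
    calls <- callRows(xRows)
    reactions <- reactions + nrow(xRows)
    if (any(calls))
      return(list(assignment = xChrom, pattern = asPattern(xRows, calls),
                  reactionsUsed = reactions, multiChromosome = FALSE))
    return(list(assignment = NA_character_,
                pattern = asPattern(xRows, calls),
                reactionsUsed = reactions, multiChromosome = FALSE))
  }
  patterns <- list()
  for (ch in posChrom) {
    rows <- panel[panel$chrom == ch, , drop = FALSE]
    done <- rows$id %in% stage1[[ch]]$id
    rest <- rows[!done, , drop = FALSE]
    restCalls <- callRows(rest)
    reactions <- reactions + nrow(rest)
    patterns[[ch]] <- asPattern(rbind(stage1[[ch]], rest),
                                c(stage1Calls[[ch]], restCalls))
  }
  list(assignment = if (length(posChrom) == 1L) posChrom else posChrom,
       pattern = do.call(rbind, patterns),
       reactionsUsed = reactions,
       multiChromosome = length(posChrom) > 1L)
}

#' Infer the introgression interval from a genotype pattern
#'
#' Inner bounds span the outermost positive primers; outer bounds are the
#' nearest flanking negative primers (or the chromosome ends). The reported
#' introgression size is the inner span; the negative-bracket width is
#' reported alongside.
#'
#' @param pattern data.frame with \code{chrom}, \code{pos}, \code{call}
#'   (one chromosome only).
#' @param chromLength chromosome length in bp.
#' @return one-row data.frame: chrom, inner_start, inner_end, outer_start,
#'   outer_end, size_bp, bracket_size_bp.
#' @export
inferInterval <- function(pattern, chromLength) {
  if (length(unique(pattern$chrom)) != 1L)
    stop("pattern must be restricted to one chromosome")
  if (!any(pattern$call))
    stop(structure(class = c("introMap_no_positive", "error", "condition"),
                   list(message = "no positive call in pattern",
                        call = sys.call(-1))))
  pattern <- pattern[order(pattern$pos), , drop = FALSE]
  pos <- pattern$pos
  innerStart <- min(pos[pattern$call])
  innerEnd <- max(pos[pattern$call])
  negL <- pos[!pattern$call & pos < innerStart]
  negR <- pos[!pattern$call & pos > innerEnd]
  data.frame(chrom = pattern$chrom[1],
             inner_start = innerStart, inner_end = innerEnd,
             outer_start = if (length(negL)) max(negL) else 0,
             outer_end = if (length(negR)) min(negR) else chromLength,
             size_bp = innerEnd - innerStart,
             bracket_size_bp = (if (length(negR)) min(negR) else chromLength) -
               (if (length(negL)) max(negL) else 0))
}

#' Detect discontinuous introgressed segments
#'
#' Maximal runs of consecutive positive calls become separate intervals; a
#' single negative call between positives splits them (the discontinuous
#' introgression signature).
#'
#' @inheritParams inferInterval
#' @return data.frame with one row per segment (columns as
#'   [inferInterval()]); zero rows when all calls are negative.
#' @export
detectSegments <- function(pattern, chromLength) {
  if (length(unique(pattern$chrom)) != 1L)
    stop("pattern must be restricted to one chromosome")
  pattern <- pattern[order(pattern$pos), , drop = FALSE]
  r <- rle(pattern$call)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (j in which(r$values)) {
    sub <- pattern
    sub$call <- seq_len(nrow(pattern)) >= starts[j] &
      seq_len(nrow(pattern)) <= ends[j]
    out[[length(out) + 1L]] <- inferInterval(sub, chromLength)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), inner_start = numeric(0),
                      inner_end = numeric(0), outer_start = numeric(0),
                      outer_end = numeric(0), size_bp = numeric(0),
                      bracket_size_bp = numeric(0)))
  do.call(rbind, out)
}

#' Mapping-table-style interval report
#'
#' Formats intervals the way introgression mapping results are reported:
#' physical position as "A to B Mb" and introgression size in Mb, one
#' decimal.
#'
#' @param strain strain name(s).
#' @param interval data.frame from [inferInterval()].
#' @return data.frame: strain, linkage_group, physical_position,
#'   introgression_size.
#' @export
intervalReport <- function(strain, interval) {
  data.frame(
    strain = strain,
    linkage_group = paste("Chrom", interval$chrom),
    physical_position = sprintf("%.1f to %.1f Mb", interval$inner_start / 1e6,
                                interval$inner_end / 1e6),
    introgression_size = sprintf("%.1f Mb", interval$size_bp / 1e6),
    stringsAsFactors = FALSE)
}

#' Expected marker-positive fraction among mutant F2 animals
#'
#' For a repulsion-phase F1 (dominant marker from one parent, recessive
#' visible mutation from the other) intercrossed, the fraction of
#' mutant-phenotype F2 that carry the marker is 2r - r^2, where r is the
#' recombination fraction between the loci.
#'
#' @param r recombination fraction(s) in `[0, 0.5]`.
#' @return expected proportion(s).
#' @examples
#' expectedF2MutantGfpFraction(0.5)  # unlinked: 0.75
#' @export
expectedF2MutantGfpFraction <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("r must lie in [0, 0.5]")
  2 * r - r^2
}

#' Two-point recombination estimate from mutant F2 counts
#'
#' Inverts 2r - r^2: r_hat = 1 - sqrt(n_neg / (n_pos + n_neg)), clipped to
#' `[0, 0.5]`.
#'
#' @param nPos marker-positive mutant count.
#' @param nNeg marker-negative mutant count.
#' @return list with \code{r_hat}, \code{n_mutant_gfp_pos},
#'   \code{n_mutant_gfp_neg}.
#' @export
estimateRecombination <- function(nPos, nNeg) {
  if (nPos + nNeg <= 0) stop("total mutant count must be positive")
  r <- 1 - sqrt(nNeg / (nPos + nNeg))
  list(r_hat = min(0.5, max(0, r)),
       n_mutant_gfp_pos = nPos, n_mutant_gfp_neg = nNeg)
}
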
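#' Panel design specification
#'
#' Tunable constraints of the species-specific panel designer. Defaults:
#' 15 pairs per chromosome, denser on the arms than in the centre
#' (weights 0.4/0.2/0.4 over physical thirds), 600 bp candidate regions,
#' specificity cutoff 50 (raw local-alignment score), 3'-end cutoff 8 bp,
#' products 150-800 bp, primers 18-27 nt with Tm 55-62 degC
#' (nearest-neighbor, 0.25 uM primer, 0.2 M effective monovalent salt),
#' GC 35-65%, homopolymer runs of 5+ rejected. On any failure the designer
#' steps 1 kb left/right of the target, alternating, up to
#' \code{maxReselectionSteps} in each direction.
#'
#' @param primersPerChromosome pairs to place per chromosome.
#' @param armDensityWeights weights of left/middle/right physical thirds
#'   (normalized to sum to 1).
#' @param candidateRegionLengthBp candidate region width in bp.
#' @param maxReselectionSteps reselection steps per direction per target.
#' @param stepBp reselection step in bp.
#' @param offtargetScoreCutoff specificity cutoff (raw score; a region
#'   scoring exactly the cutoff is retained).
#' @param threePrimeCutoffBp longest tolerated 3'-anchored exact match.
#' @param productSizeRange numeric \code{c(min, max)} product size in bp.
#' @param primerLengthRange primer length range in nt.
#' @param tmRange melting-temperature window in degC.
#' @param gcRange GC-content window (proportions).
#' @param maxHomopolymer longest tolerated single-base run.
#' @return a validated list of class \code{panelSpec}.
#' @export
panelSpec <- function(primersPerChromosome = 15,
                      armDensityWeights = c(left = 0.4, middle = 0.2, right = 0.4),
                      candidateRegionLengthBp = 600,
                      maxReselectionSteps = 50, stepBp = 1000,
                      offtargetScoreCutoff = 50, threePrimeCutoffBp = 8,
                      productSizeRange = c(150, 800),
                      primerLengthRange = c(18, 27),
                      tmRange = c(55, 62), gcRange = c(0.35, 0.65),
                      maxHomopolymer = 4) {
  stopifnot(length(armDensityWeights) == 3L, all(armDensityWeights >= 0),
            offtargetScoreCutoff > 0, threePrimeCutoffBp >= 0,
            primersPerChromosome >= 1, productSizeRange[1] < productSizeRange[2])
  spec <- list(primersPerChromosome = primersPerChromosome,
               armDensityWeights = armDensityWeights / sum(armDensityWeights),
               candidateRegionLengthBp = candidateRegionLengthBp,
               maxReselectionSteps = maxReselectionSteps, stepBp = stepBp,
               offtargetScoreCutoff = offtargetScoreCutoff,
               threePrimeCutoffBp = threePrimeCutoffBp,
               productSizeRange = productSizeRange,
               primerLengthRange = primerLengthRange,
               tmRange = tmRange, gcRange = gcRange,
               maxHomopolymer = maxHomopolymer)
  class(spec) <- "panelSpec"
  spec
}

#' Evenly spaced, arm-biased target layout for one chromosome
#'
#' Splits the chromosome into physical thirds (left arm, middle, right arm),
#' allocates the requested pair count by the density weights (remainders to
#' the largest fractional shares, ties leftmost) and spaces targets evenly
#' within each third.
#'
#' @param chromLength chromosome length in bp.
#' @param n number of targets.
#' @param weights length-3 density weights.
#' @return data.frame with \code{pos} (0-based bp) and \code{arm}.
#' @export
targetPositions <- function(chromLength, n, weights = c(0.4, 0.2, 0.4)) {
  weights <- weights / sum(weights)
  raw <- n * weights
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  arms <- c("left", "middle", "right")
  do.call(rbind, lapply(1:3, function(i) {
    k <- counts[i]
    if (k == 0) return(NULL)
    third <- chromLength / 3
    data.frame(pos = (i - 1) * third + (seq_len(k) - 0.5) / k * third,
               arm = arms[i])
  }))
}

## Intron+intergenic minus repeats, as disjoint sorted 1-based IRanges.
.allowedRanges <- function(annotation, chrom, chromLength) {
  ft <- featureTable(annotation)
  ft <- ft[ft$chrom == chrom, , drop = FALSE]
  gene <- ft[ft$kind %in% c("exon", "intron"), , drop = FALSE]
  reps <- ft[ft$kind == "repeat", , drop = FALSE]
  geneIv <- IRanges::reduce(IRanges::IRanges(gene$start + 1, gene$end))
  interIv <- IRanges::setdiff(IRanges::IRanges(1, chromLength), geneIv)
  intronIv <- IRanges::reduce(IRanges::IRanges(
    ft$start[ft$kind == "intron"] + 1, ft$end[ft$kind == "intron"]))
  allowed <- IRanges::reduce(IRanges::union(interIv, intronIv))
  if (nrow(reps))
    allowed <- IRanges::setdiff(allowed,
                                IRanges::IRanges(reps$start + 1, reps$end))
  allowed
}

#' Select the nearest qualifying candidate region around a target
#'
#' Returns the nearest interval of the spec's candidate width that lies
#' wholly in intron or intergenic sequence and overlaps no repeat feature.
#' The search alternates right/left of the target in fixed steps; when no
#' qualifying interval exists within the step budget a region-exhausted
#' error (condition class \code{introMap_region_exhausted}) is signalled.
#'
#' @param annotation GRanges annotation with a \code{kind} column.
#' @param chrom chromosome name.
#' @param targetPos 0-based target position in bp.
#' @param spec a [panelSpec()].
#' @param chromLength chromosome length (taken from the annotation
#'   seqlengths when missing).
#' @return list with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) and \code{offsetSteps}.
#' @export
selectCandidateRegion <- function(annotation, chrom, targetPos,
                                  spec = panelSpec(), chromLength = NULL) {
  if (is.null(chromLength)) {
    chromLength <- GenomeInfoDb::seqlengths(annotation)[chrom]
    if (is.na(chromLength))
      stop("chromLength not given and not available from the annotation")
  }
  if (targetPos < 0 || targetPos >= chromLength)
    stop("target position outside chromosome ", chrom)
  allowed <- .allowedRanges(annotation, chrom, chromLength)
  res <- .regionAt(allowed, targetPos, spec, chromLength)
  if (is.null(res))
    stop(structure(class = c("introMap_region_exhausted", "error", "condition"),
                   list(message = sprintf(
                     "no candidate region of %d bp within %d steps of %s:%0.f",
                     spec$candidateRegionLengthBp, spec$maxReselectionSteps,
                     chrom, targetPos), call = sys.call(-1))))
  c(list(chrom = chrom), res)
}

## First qualifying window over the alternating offset walk, or NULL.
.regionAt <- function(allowed, targetPos, spec, chromLength) {
  for (k in .offsetSequence(spec$maxReselectionSteps)) {
    win <- .windowAt(allowed, targetPos + k * spec$stepBp, spec, chromLength)
    if (!is.null(win)) return(c(win, list(offsetSteps = k)))
  }
  NULL
}

.offsetSequence <- function(maxSteps) {
  if (maxSteps == 0) return(0L)
  c(0L, as.vector(rbind(seq_len(maxSteps), -seq_len(maxSteps))))
}

## Window of spec width centred at `center` (0-based), if wholly allowed.
.windowAt <- function(allowed, center, spec, chromLength) {
  w <- spec$candidateRegionLengthBp
  s0 <- round(center - w / 2)
  if (s0 < 0 || s0 + w > chromLength) return(NULL)
  s1 <- s0 + 1  # 1-based
  i <- findInterval(s1, IRanges::start(allowed))
  if (i >= 1 && IRanges::end(allowed)[i] >= s0 + w)
    list(start = s0, end = s0 + w)
  else NULL
}

## SantaLucia unified nearest-neighbor parameters (dH kcal/mol, dS cal/mol/K)
.NN_H <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
.NN_S <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
.TM_CONC <- 2.5e-7   # 0.25 uM primer
.TM_NA <- 0.2        # effective monovalent salt, M

#' Nearest-neighbor primer melting temperature
#'
#' Unified nearest-neighbor thermodynamics with a logarithmic salt
#' correction, at 0.25 uM primer and 0.2 M effective monovalent cation
#' (PCR buffer with Mg). Strand-symmetric, so a primer and its reverse
#' complement share a Tm.
#'
#' @param x character vector of primer sequences.
#' @return numeric vector of melting temperatures in degC.
#' @export
primerTm <- function(x) {
  vapply(x, function(s) {
    v <- strsplit(toupper(s), "")[[1]]
    di <- paste0(v[-length(v)], v[-1])
    gcInit <- function(b) if (b %in% c("G", "C")) c(0.1, -2.8) else c(2.3, 4.1)
    i1 <- gcInit(v[1]); i2 <- gcInit(v[length(v)])
    dH <- sum(.NN_H[di]) + i1[1] + i2[1]
    dS <- sum(.NN_S[di]) + i1[2] + i2[2]
    dH * 1000 / (dS + 1.9872 * log(.TM_CONC / 4)) - 273.15 +
      16.6 * log10(.TM_NA)
  }, numeric(1), USE.NAMES = FALSE)
}

## All primer candidates within a region string satisfying length/Tm/GC/run
## constraints; prefix-sum evaluation over every (start, length).
.primerCandidates <- function(regionSeq, spec) {
  v <- strsplit(regionSeq, "")[[1]]
  w <- length(v)
  lmin <- spec$primerLengthRange[1]; lmax <- spec$primerLengthRange[2]
  if (w < lmin) return(NULL)
  di <- paste0(v[-w], v[-1])
  csH <- c(0, cumsum(.NN_H[di]))
  csS <- c(0, cumsum(.NN_S[di]))
  isGC <- v %in% c("G", "C")
  csGC <- c(0, cumsum(isGC))
  k <- spec$maxHomopolymer  # a run of k+1 identical bases disqualifies
  runBad <- rep(TRUE, w - k)
  for (d in seq_len(k)) runBad <- runBad & v[1:(w - k)] == v[(1 + d):(w - k + d)]
  csRun <- c(0, cumsum(runBad))
  hInit <- ifelse(isGC, 0.1, 2.3)
  sInit <- ifelse(isGC, -2.8, 4.1)
  denomC <- 1.9872 * log(.TM_CONC / 4)
  out <- vector("list", lmax - lmin + 1)
  for (l in lmin:lmax) {
    if (w < l) next
    st <- seq_len(w - l + 1)
    en <- st + l - 1
    dH <- csH[en] - csH[st] + hInit[st] + hInit[en]
    dS <- csS[en] - csS[st] + sInit[st] + sInit[en]
    tm <- dH * 1000 / (dS + denomC) - 273.15 + 16.6 * log10(.TM_NA)
    gc <- (csGC[en + 1] - csGC[st]) / l
    hasRun <- (csRun[en - k + 1] - csRun[st]) > 0  # any (k+1)-run starting in window
    ok <- tm >= spec$tmRange[1] & tm <= spec$tmRange[2] &
      gc >= spec$gcRange[1] & gc <= spec$gcRange[2] & !hasRun
    if (any(ok))
      out[[l - lmin + 1]] <- data.frame(start = st[ok], len = l, tm = tm[ok])
  }
  cand <- do.call(rbind, out)
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  cand
}

#' Pick the best primer pair within a candidate region
#'
#' Enumerates every primer placement satisfying the length, Tm, GC and
#' homopolymer constraints, then every facing pair with a product size in
#' range, and returns the pair with the smallest left/right Tm difference
#' (ties: leftmost left primer, then smallest right end). Deterministic for
#' fixed input; returns \code{NULL} when no pair satisfies the constraints.
#'
#' @param regionSeq region sequence (character).
#' @param spec a [panelSpec()].
#' @param chrom chromosome name recorded on the pair.
#' @param regionStart 0-based start of the region on the chromosome.
#' @param arm arm label recorded on the pair.
#' @return one-row data.frame (see [designPanel()] for columns) or NULL.
#' @export
pickPrimerPair <- function(regionSeq, spec = panelSpec(),
                           chrom = NA_character_, regionStart = 0,
                           arm = NA_character_) {
  cand <- .primerCandidates(regionSeq, spec)
  if (is.null(cand)) return(NULL)
  mid <- mean(spec$tmRange)
  if (nrow(cand) > 400L) {
    ord <- order(abs(cand$tm - mid), cand$start, cand$len)
    cand <- cand[ord[1:400], ]
  }
  iL <- rep(seq_len(nrow(cand)), times = nrow(cand))
  iR <- rep(seq_len(nrow(cand)), each = nrow(cand))
  prod <- cand$start[iR] + cand$len[iR] - cand$start[iL]
  ok <- prod >= spec$productSizeRange[1] & prod <= spec$productSizeRange[2] &
    cand$start[iR] > cand$start[iL] + cand$len[iL]
  if (!any(ok)) return(NULL)
  iL <- iL[ok]; iR <- iR[ok]
  tmdiff <- abs(cand$tm[iL] - cand$tm[iR])
  best <- order(tmdiff, cand$start[iL], cand$start[iR] + cand$len[iR])[1]
  bL <- cand[iL[best], ]; bR <- cand[iR[best], ]
  leftSeq <- substr(regionSeq, bL$start, bL$start + bL$len - 1)
  rightPlus <- substr(regionSeq, bR$start, bR$start + bR$len - 1)
  data.frame(
    chrom = chrom,
    left_start = regionStart + bL$start - 1,
    right_end = regionStart + bR$start + bR$len - 1,
    left_seq = leftSeq,
    right_seq = .revcompChar(rightPlus),
    product_size = bR$start + bR$len - bL$start,
    tm_left = bL$tm, tm_right = bR$tm,
    arm = arm, status = "candidate",
    stringsAsFactors = FALSE)
}

#' Design a species-specific primer panel
#'
#' For each chromosome, lays out arm-biased targets, and for each target
#' walks candidate regions outward from the target until one (i) lies wholly
#' in intron/intergenic sequence clear of repeats, (ii) has no local
#' alignment against the recipient scoring more than the cutoff, (iii)
#' yields a primer pair under the physical constraints, and (iv) both
#' primers pass the 3'-end filter against windows of local similarity in the
#' recipient. Every rejection is logged with its cause. A chromosome
#' yielding fewer than 3 pairs raises a panel-infeasible error (condition
#' class \code{introMap_panel_infeasible}).
#'
#' @param donor,recipient [Genome-class] objects with sequence.
#' @param annotation GRanges annotation of the donor.
#' @param map optional [GeneticMap-class] (recorded, not used for layout).
#' @param spec a [panelSpec()].
#' @param verbose print progress.
#' @return list with \code{panel} (data.frame: id, chrom, left_start,
#'   right_end, left_seq, right_seq, product_size, tm_left, tm_right, arm,
#'   status, max_offtarget_score, max_three_prime_match, target_pos,
#'   offset_steps) and \code{log} (data.frame of rejections).
#' @export
designPanel <- function(donor, recipient, annotation, map = NULL,
                        spec = panelSpec(), verbose = FALSE) {
  stopifnot(is(donor, "Genome"), is(recipient, "Genome"))
  if (!hasSequence(donor) || !hasSequence(recipient))
    stop("panel design requires genome sequences")
  if (!all(chromNames(donor) %in% chromNames(recipient)))
    stop("recipient genome lacks chromosomes of the donor")
  recipSeqs <- recipient@sequences
  panel <- list()
  logRows <- list()
  note <- function(chrom, target, k, stage, detail) {
    logRows[[length(logRows) + 1L]] <<- data.frame(
      chrom = chrom, target_pos = target, offset_steps = k,
      stage = stage, detail = detail, stringsAsFactors = FALSE)
  }
  for (ch in chromNames(donor)) {
    L <- chromLengths(donor)[[ch]]
    chromChar <- as.character(donor@sequences[[ch]])
    allowed <- .allowedRanges(annotation, ch, L)
    targets <- targetPositions(L, spec$primersPerChromosome,
                               spec$armDensityWeights)
    found <- 0L
    for (t in seq_len(nrow(targets))) {
      tp <- targets$pos[t]
      hit <- NULL
      for (k in .offsetSequence(spec$maxReselectionSteps)) {
        win <- .windowAt(allowed, tp + k * spec$stepBp, spec, L)
        if (is.null(win)) { note(ch, tp, k, "region", "not in intron/intergenic clear of repeats"); next }
        regionSeq <- substr(chromChar, win$start + 1, win$end)
        sc <- maxLocalAlignmentScore(regionSeq, recipSeqs, method = "seeded")
        if (sc > spec$offtargetScoreCutoff) {
          note(ch, tp, k, "specificity", sprintf("score %d > %d", sc,
                                                 spec$offtargetScoreCutoff))
          next
        }
        pair <- pickPrimerPair(regionSeq, spec, chrom = ch,
                               regionStart = win$start, arm = targets$arm[t])
        if (is.null(pair)) { note(ch, tp, k, "primer", "no pair satisfies constraints"); next }
        tp3 <- c(longestThreePrimeMatch(pair$left_seq, recipSeqs, method = "seeded"),
                 longestThreePrimeMatch(pair$right_seq, recipSeqs, method = "seeded"))
        if (max(tp3) > spec$threePrimeCutoffBp) {
          note(ch, tp, k, "three_prime", sprintf("3' match %d > %d", max(tp3),
                                                 spec$threePrimeCutoffBp))
          next
        }
        pair$max_offtarget_score <- max(
          maxLocalAlignmentScore(pair$left_seq, recipSeqs, method = "seeded"),
          maxLocalAlignmentScore(pair$right_seq, recipSeqs, method = "seeded"))
        pair$max_three_prime_match <- max(tp3)
        pair$target_pos <- tp
        pair$offset_steps <- k
        hit <- pair
        break
      }
      if (is.null(hit)) {
        note(ch, tp, NA, "exhausted", "no qualifying region for this target")
      } else {
        found <- found + 1L
        hit$id <- sprintf("%s_%02d", ch, found)
        panel[[length(panel) + 1L]] <- hit
      }
      if (verbose) message(sprintf("%s target %.0f: %s", ch, tp,
                                   if (is.null(hit)) "failed" else hit$id))
    }
    if (found < 3L)
      stop(structure(class = c("introMap_panel_infeasible", "error", "condition"),
                     list(message = sprintf(
                       "chromosome %s yielded %d primer pairs (minimum 3)",
                       ch, found), call = sys.call(-1))))
  }
  panel <- do.call(rbind, panel)
  panel <- panel[c("id", setdiff(names(panel), "id"))]
  rownames(panel) <- NULL
  log <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(chrom = character(0), target_pos = numeric(0),
               offset_steps = numeric(0), stage = character(0),
               detail = character(0))
  list(panel = panel, log = log)
}

#' Audit a panel by in-silico PCR against both genomes
#'
#' Each pair is amplified in sequence mode against the donor and the
#' recipient. Pairs producing a product from the recipient are marked
#' \code{discarded} (cross-amplifying); pairs amplifying the donor only are
#' \code{retained}. Retained = candidates - cross-amplifying.
#'
#' @param panel panel data.frame (see [designPanel()]).
#' @param donor,recipient [Genome-class] objects with sequence.
#' @param maxProductBp largest product considered amplifiable.
#' @return list with \code{panel} (statuses updated, plus
#'   \code{amplifies_donor}/\code{amplifies_recipient} columns) and
#'   \code{counts} (candidates, cross_amplifying, retained).
#' @export
validatePanel <- function(panel, donor, recipient, maxProductBp = 2000) {
  stopifnot(nrow(panel) > 0)
  ampD <- logical(nrow(panel))
  ampR <- logical(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    ampD[i] <- insilicoPcrSequence(donor, panel[i, ], maxProductBp)$amplified
    ampR[i] <- insilicoPcrSequence(recipient, panel[i, ], maxProductBp)$amplified
  }
  panel$amplifies_donor <- ampD
  panel$amplifies_recipient <- ampR
  panel$status <- ifelse(ampR, "discarded", ifelse(ampD, "retained", "failed"))
  list(panel = panel,
       counts = c(candidates = nrow(panel),
                  cross_amplifying = sum(ampR),
                  retained = nrow(panel) - sum(ampR)))
}

#' Adjacent-gap spacing statistics of a panel
#'
#' Gaps between consecutive retained pairs (midpoint coordinates) per
#' chromosome; chromosomes with fewer than two retained pairs are omitted
#' with a warning.
#'
#' @param panel panel data.frame.
#' @return list with \code{perChromosome} (chrom, n, mean_gap, max_gap) and
#'   \code{globalMeanGap}.
#' @export
panelSpacingStats <- function(panel) {
  keep <- panel[panel$status %in% c("candidate", "retained"), , drop = FALSE]
  keep$mid <- (keep$left_start + keep$right_end) / 2
  rows <- list()
  gapsAll <- numeric(0)
  for (ch in unique(keep$chrom)) {
    s <- keep[keep$chrom == ch, ]
    if (nrow(s) < 2L) {
      warning("fewer than 2 retained pairs on ", ch, "; omitted")
      next
    }
    g <- diff(sort(s$mid))
    gapsAll <- c(gapsAll, g)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, n = nrow(s), mean_gap = mean(g), max_gap = max(g))
  }
  list(perChromosome = do.call(rbind, rows),
       globalMeanGap = if (length(gapsAll)) mean(gapsAll) else NA_real_)
}

#' Coordinate-only panel with the standard layout
#'
#' Builds a panel of primer-pair coordinates (no sequences) laid out like
#' [designPanel()] would: arm-biased targets, a fixed product size centred
#' on each target. Sufficient for coordinate-mode genotyping and for
#' reaction-count arithmetic.
#'
#' @param genome a [Genome-class] (coordinate-only is fine).
#' @param primersPerChromosome pairs per autosome.
#' @param xPrimers pairs on the X (default: same as autosomes).
#' @param armDensityWeights density weights over physical thirds.
#' @param productSize product size in bp.
#' @return panel data.frame with status \code{"retained"}.
#' @export
coordinatePanel <- function(genome, primersPerChromosome = 15,
                            xPrimers = primersPerChromosome,
                            armDensityWeights = c(0.4, 0.2, 0.4),
                            productSize = 500) {
  rows <- list()
  for (ch in chromNames(genome)) {
    L <- chromLengths(genome)[[ch]]
    n <- if (!is.na(sexChromosome(genome)) && ch == sexChromosome(genome))
      xPrimers else primersPerChromosome
    tg <- targetPositions(L, n, armDensityWeights)
    ls <- pmax(0, round(tg$pos - productSize / 2))
    re <- pmin(L, ls + productSize)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%s_%02d", ch, seq_len(nrow(tg))), chrom = ch,
      left_start = ls, right_end = re, left_seq = NA_character_,
      right_seq = NA_character_, product_size = re - ls, arm = tg$arm,
      status = "retained", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a panel as TSV
#'
#' @param panel panel data.frame.
#' @param path file path.
#' @export
writePanel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export primer binding sites as BED
#'
#' @param panel panel data.frame with sequences.
#' @param path output BED file.
#' @export
writePanelBed <- function(panel, path) {
  lens <- nchar(panel$left_seq)
  lens[is.na(lens)] <- 20L
  rlen <- nchar(panel$right_seq)
  rlen[is.na(rlen)] <- 20L
  gr <- GenomicRanges::GRanges(
    seqnames = rep(panel$chrom, 2),
    ranges = IRanges::IRanges(
      start = c(panel$left_start + 1, panel$right_end - rlen + 1),
      end = c(panel$left_start + lens, panel$right_end)),
    strand = rep(c("+", "-"), each = nrow(panel)),
    name = paste0(rep(panel$id, 2), rep(c("_L", "_R"), each = nrow(panel))))
  rtracklayer::export.bed(gr, path)
  invisible(path)
}
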
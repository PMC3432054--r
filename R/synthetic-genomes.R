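#' Divergence configuration for the synthetic sister-genome pair
#'
#' The recipient genome is derived from the donor by class-specific
#' substitution (exons and repeats conserved, non-coding sequence strongly
#' diverged) and non-exonic indels, without simulating a common ancestor:
#' downstream methods only need the divergence contrast. The default
#' non-exonic substitution rate (0.45) makes most 600 bp non-coding regions
#' fall under the local-alignment score-50 specificity cutoff while still
#' leaving roughly one region in ten above it, so the primer-design loop
#' exercises its reselection path at a realistic rate; non-coding sequence
#' between the modelled species pair is largely unalignable, which this
#' emulates.
#'
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @param nAutosomes autosome count (an X is always added).
#' @param chromLengthBp chromosome length in bp.
#' @param exonFraction fraction of each chromosome covered by exons.
#' @param repeatFraction fraction covered by (shared, conserved) tandem
#'   repeat tracts placed in intergenic sequence.
#' @param substRateExonic per-base substitution probability in exons and
#'   repeats (coding/repeat conservation).
#' @param substRateNonexonic per-base substitution probability elsewhere;
#'   must be >= the exonic rate.
#' @param indelRateNonexonic per-base indel initiation probability in
#'   non-exonic, non-repeat sequence.
#' @param meanIndelBp mean indel length (geometric).
#' @param contaminantContigs number of extra recipient-only contigs built
#'   from unrelated random sequence carrying donor-like exons (emulating
#'   cross-species contamination of a draft assembly).
#' @param sharedHaplotypeFraction fraction of each chromosome copied
#'   unchanged from donor into recipient in contiguous tracts (emulating
#'   wild introgression between the species).
#' @return a validated list of class \code{divergenceConfig}.
#' @export
divergenceConfig <- function(seed = 1, nAutosomes = 5, chromLengthBp = 15e6,
                             exonFraction = 0.25, repeatFraction = 0.10,
                             substRateExonic = 0.02,
                             substRateNonexonic = 0.45,
                             indelRateNonexonic = 0.02, meanIndelBp = 6,
                             contaminantContigs = 0,
                             sharedHaplotypeFraction = 0) {
  cfg <- list(seed = as.integer(seed), nAutosomes = as.integer(nAutosomes),
              chromLengthBp = as.numeric(chromLengthBp),
              exonFraction = exonFraction, repeatFraction = repeatFraction,
              substRateExonic = substRateExonic,
              substRateNonexonic = substRateNonexonic,
              indelRateNonexonic = indelRateNonexonic,
              meanIndelBp = meanIndelBp,
              contaminantContigs = as.integer(contaminantContigs),
              sharedHaplotypeFraction = sharedHaplotypeFraction)
  props <- c(cfg$exonFraction, cfg$repeatFraction, cfg$substRateExonic,
             cfg$substRateNonexonic, cfg$indelRateNonexonic,
             cfg$sharedHaplotypeFraction)
  if (any(props < 0 | props > 1))
    stop("all proportions and rates must lie in [0, 1]")
  if (cfg$substRateExonic > cfg$substRateNonexonic)
    stop("substRateExonic must not exceed substRateNonexonic (coding conservation)")
  if (cfg$exonFraction + cfg$repeatFraction > 0.9)
    stop("exonFraction + repeatFraction exceed chromosome capacity")
  if (cfg$meanIndelBp < 1) stop("meanIndelBp must be >= 1")
  class(cfg) <- "divergenceConfig"
  cfg
}

.BASES <- c("A", "C", "G", "T")

.randomDNA <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

## Gene/repeat layout for one chromosome; 0-based half-open coordinates.
.layoutChromosome <- function(L, exonFraction, repeatFraction) {
  feats <- list()
  pos <- 200
  while (TRUE) {
    nEx <- sample(3:7, 1)
    exLens <- sample(150:350, nEx, replace = TRUE)
    inLens <- if (nEx > 1) sample(250:600, nEx - 1, replace = TRUE) else integer(0)
    span <- sum(exLens) + sum(inLens)
    gap <- max(250, round(sum(exLens) / max(exonFraction, 1e-3) - span))
    gap <- round(gap * stats::runif(1, 0.8, 1.2))
    start <- pos + gap
    if (start + span > L - 200) break
    p <- start
    for (i in seq_len(nEx)) {
      feats[[length(feats) + 1L]] <- c(p, p + exLens[i], 1)  # exon
      p <- p + exLens[i]
      if (i < nEx) {
        feats[[length(feats) + 1L]] <- c(p, p + inLens[i], 2)  # intron
        p <- p + inLens[i]
      }
    }
    pos <- p
  }
  m <- do.call(rbind, feats)
  ann <- data.frame(start = m[, 1], end = m[, 2],
                    kind = c("exon", "intron")[m[, 3]])
  ## repeat tracts go into intergenic gaps, away from gene margins
  geneIv <- IRanges::reduce(IRanges::IRanges(ann$start + 1, ann$end))
  inter <- IRanges::setdiff(IRanges::IRanges(1, L), geneIv)
  inter <- inter[IRanges::width(inter) > 400]
  targetRep <- repeatFraction * L
  placed <- 0
  reps <- list()
  ord <- sample(length(inter))
  i <- 1
  while (placed < targetRep && i <= length(inter) * 4) {
    iv <- inter[ord[(i - 1) %% length(inter) + 1]]
    len <- sample(120:260, 1)
    lo <- IRanges::start(iv) + 50
    hi <- IRanges::end(iv) - 50 - len
    if (hi > lo) {
      s <- sample(lo:hi, 1)
      newIv <- c(s - 1, s - 1 + len)  # 0-based
      clash <- any(vapply(reps, function(r)
        newIv[1] < r[2] + 50 && r[1] < newIv[2] + 50, logical(1)))
      if (!clash) {
        reps[[length(reps) + 1L]] <- newIv
        placed <- placed + len
      }
    }
    i <- i + 1
  }
  if (length(reps)) {
    rm <- do.call(rbind, reps)
    ann <- rbind(ann, data.frame(start = rm[, 1], end = rm[, 2],
                                 kind = "repeat"))
  }
  ann[order(ann$start), , drop = FALSE]
}

## Donor chromosome string: random background with tandem-repeat tracts.
.buildDonorChromosome <- function(L, ann) {
  repA <- ann[ann$kind == "repeat", , drop = FALSE]
  if (nrow(repA) == 0L) return(.randomDNA(L))
  repA <- repA[order(repA$start), ]
  pieces <- character(0)
  cur <- 0
  for (i in seq_len(nrow(repA))) {
    if (repA$start[i] > cur)
      pieces <- c(pieces, .randomDNA(repA$start[i] - cur))
    motif <- .randomDNA(6)
    len <- repA$end[i] - repA$start[i]
    pieces <- c(pieces, substr(strrep(motif, ceiling(len / 6)), 1, len))
    cur <- repA$end[i]
  }
  if (cur < L) pieces <- c(pieces, .randomDNA(L - cur))
  paste(pieces, collapse = "")
}

## Sample k distinct 1-based positions uniformly within an IRanges set.
.samplePosInRanges <- function(ranges, k) {
  w <- IRanges::width(ranges)
  total <- sum(w)
  if (k == 0L || total == 0L) return(integer(0))
  k <- min(k, total)
  idx <- sample.int(total, k)
  cum <- c(0, cumsum(as.numeric(w)))
  ri <- findInterval(idx - 0.5, cum)
  IRanges::start(ranges)[ri] + (idx - cum[ri]) - 1L
}

## Substitute letters at 1-based positions (never back to the original base).
.substituteAt <- function(dna, pos) {
  if (length(pos) == 0L) return(dna)
  orig <- as.character(Biostrings::extractAt(dna, IRanges::IRanges(pos, pos)))
  code <- match(orig, .BASES)
  newb <- .BASES[((code - 1L + sample.int(3L, length(pos), replace = TRUE)) %% 4L) + 1L]
  Biostrings::replaceLetterAt(dna, pos, paste(newb, collapse = ""))
}

## Apply substitutions + indels to one donor chromosome; returns character.
.mutateChromosome <- function(donorChar, annChrom, cfg) {
  L <- nchar(donorChar)
  conserved <- IRanges::reduce(with(
    annChrom[annChrom$kind %in% c("exon", "repeat"), , drop = FALSE],
    IRanges::IRanges(start + 1, end)))
  nonex <- IRanges::setdiff(IRanges::IRanges(1, L), conserved)
  dna <- Biostrings::DNAString(donorChar)
  nC <- stats::rbinom(1, sum(IRanges::width(conserved)), cfg$substRateExonic)
  nN <- stats::rbinom(1, sum(IRanges::width(nonex)), cfg$substRateNonexonic)
  pos <- c(.samplePosInRanges(conserved, nC), .samplePosInRanges(nonex, nN))
  dna <- .substituteAt(dna, pos)
  s <- as.character(dna)
  ## indels, restricted to non-conserved sequence so annotation stays valid
  nI <- stats::rbinom(1, sum(IRanges::width(nonex)), cfg$indelRateNonexonic)
  if (nI > 0L) {
    ip <- sort(.samplePosInRanges(nonex, nI))
    lens <- stats::rgeom(length(ip), 1 / cfg$meanIndelBp) + 1L
    isDel <- stats::runif(length(ip)) < 0.5
    consStarts <- IRanges::start(conserved)
    ## clip deletions so they stop before the next conserved block
    nxt <- consStarts[findInterval(ip, consStarts) + 1L]
    nxt[is.na(nxt)] <- L + 1L
    lens <- ifelse(isDel, pmin(lens, pmax(nxt - ip - 1L, 0L), L - ip), lens)
    keepStarts <- numeric(0); keepEnds <- numeric(0)
    insAfter <- integer(0)  # index into pieces after which an insertion goes
    insLens <- integer(0)
    cur <- 1
    for (j in seq_along(ip)) {
      p <- ip[j]
      if (p < cur) next
      if (isDel[j]) {
        if (lens[j] == 0L) next
        keepStarts <- c(keepStarts, cur); keepEnds <- c(keepEnds, p - 1)
        cur <- p + lens[j]
      } else {
        keepStarts <- c(keepStarts, cur); keepEnds <- c(keepEnds, p)
        insAfter <- c(insAfter, length(keepStarts))
        insLens <- c(insLens, lens[j])
        cur <- p + 1
      }
    }
    keepStarts <- c(keepStarts, cur); keepEnds <- c(keepEnds, L)
    pieces <- substring(s, keepStarts, keepEnds)
    if (length(insAfter)) {
      ins <- vapply(insLens, .randomDNA, character(1))
      out <- character(length(pieces) + length(ins))
      slot <- seq_along(pieces) + findInterval(seq_along(pieces) - 0.5, insAfter)
      out[slot] <- pieces
      out[insAfter + seq_along(insAfter)] <- ins
      pieces <- out
    }
    s <- paste(pieces, collapse = "")
  }
  s
}

#' Generate a divergence-structured sister-genome pair
#'
#' Builds a donor genome (random background, laid-out genes with conserved
#' exons, shared tandem-repeat tracts) plus its annotation, then derives the
#' recipient by class-specific substitution and non-exonic indels. Optionally
#' adds contaminant contigs to the recipient and copies shared haplotype
#' tracts from the donor. Identical seeds give byte-identical output.
#'
#' @param config a [divergenceConfig()].
#' @return list with elements \code{donor} and \code{recipient}
#'   ([Genome-class]), \code{annotation} (GRanges on the donor),
#'   \code{sharedTracts} (data.frame of 0-based donor-coordinate tracts,
#'   empty unless \code{sharedHaplotypeFraction > 0}) and \code{config}.
#' @examples
#' pair <- generateSisterPair(divergenceConfig(seed = 7, nAutosomes = 1,
#'                                             chromLengthBp = 5e4))
#' pair$donor
#' @export
generateSisterPair <- function(config = divergenceConfig()) {
  stopifnot(inherits(config, "divergenceConfig"))
  set.seed(config$seed)
  chroms <- c(as.character(utils::as.roman(seq_len(config$nAutosomes))), "X")
  donorSeqs <- character(0)
  recipSeqs <- character(0)
  annAll <- list()
  for (ch in chroms) {
    L <- config$chromLengthBp
    ann <- .layoutChromosome(L, config$exonFraction, config$repeatFraction)
    dch <- .buildDonorChromosome(L, ann)
    rch <- .mutateChromosome(dch, ann, config)
    donorSeqs[ch] <- dch
    recipSeqs[ch] <- rch
    ann$chrom <- ch
    annAll[[ch]] <- ann
  }
  ## contaminant contigs: unrelated background + donor-like exons
  if (config$contaminantContigs > 0L) {
    donorAnn <- annAll[[chroms[1]]]
    exons <- donorAnn[donorAnn$kind == "exon", , drop = FALSE]
    for (k in seq_len(config$contaminantContigs)) {
      cl <- max(2e4, round(config$chromLengthBp * 0.05))
      contig <- .randomDNA(cl)
      nCopy <- min(10L, nrow(exons))
      pick <- sample(nrow(exons), nCopy)
      at <- sort(sample(seq(1000, cl - 2000), nCopy))
      for (i in seq_len(nCopy)) {
        ex <- exons[pick[i], ]
        exSeq <- substr(donorSeqs[[chroms[1]]], ex$start + 1, ex$end)
        exSeq <- as.character(.substituteAt(
          Biostrings::DNAString(exSeq),
          .samplePosInRanges(IRanges::IRanges(1, nchar(exSeq)),
                             stats::rbinom(1, nchar(exSeq), config$substRateExonic))))
        substr(contig, at[i], at[i] + nchar(exSeq) - 1) <- exSeq
      }
      recipSeqs[paste0("contam_", k)] <- contig
    }
  }
  annDf <- do.call(rbind, annAll)
  annotation <- GenomicRanges::GRanges(
    seqnames = annDf$chrom,
    ranges = IRanges::IRanges(annDf$start + 1, annDf$end),
    strand = "*", kind = annDf$kind,
    seqinfo = GenomeInfoDb::Seqinfo(chroms, as.integer(rep(config$chromLengthBp,
                                                           length(chroms)))))
  donor <- Genome("donor", sequences = donorSeqs, sexChrom = "X")
  recipient <- Genome("recipient", sequences = recipSeqs, sexChrom = "X")
  tracts <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  if (config$sharedHaplotypeFraction > 0) {
    inj <- injectSharedHaplotypes(recipient, donor,
                                  config$sharedHaplotypeFraction,
                                  seed = config$seed + 1L)
    recipient <- inj$genome
    tracts <- inj$tracts
  }
  list(donor = donor, recipient = recipient, annotation = annotation,
       sharedTracts = tracts, config = config)
}

#' Copy shared haplotype tracts from donor into recipient
#'
#' Replaces the stated fraction of each recipient chromosome with the donor's
#' homologous sequence in contiguous tracts, emulating wild introgression
#' between the species pair: primers falling inside a tract lose their
#' species specificity. Tract coordinates are returned in donor coordinates
#' as ground truth.
#'
#' @param recipient,donor [Genome-class] objects with sequence.
#' @param fraction fraction of each chromosome to replace, in `[0, 1]`.
#' @param seed integer seed for tract placement.
#' @return list with \code{genome} (modified recipient) and \code{tracts}
#'   (data.frame \code{chrom}, \code{start}, \code{end}; 0-based donor
#'   coordinates).
#' @export
injectSharedHaplotypes <- function(recipient, donor, fraction, seed = 1) {
  stopifnot(is(recipient, "Genome"), is(donor, "Genome"),
            fraction >= 0, fraction <= 1)
  if (fraction == 0)
    return(list(genome = recipient,
                tracts = data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0))))
  set.seed(seed)
  rseqs <- recipient@sequences
  tracts <- list()
  for (ch in chromNames(donor)) {
    Ld <- chromLengths(donor)[[ch]]
    Lr <- Biostrings::width(rseqs[ch])
    if (fraction >= 1) {
      rseqs[[ch]] <- donor@sequences[[ch]]
      tracts[[ch]] <- data.frame(chrom = ch, start = 0, end = Ld)
      next
    }
    target <- fraction * Ld
    meanLen <- max(2e3, Ld / 10)
    nT <- max(1L, round(target / meanLen))
    lens <- round(target / nT * stats::runif(nT, 0.7, 1.3))
    lens[1] <- max(1, round(target - sum(lens[-1])))
    acc <- matrix(numeric(0), ncol = 2)
    for (len in lens) {
      for (try in 1:100) {
        s <- floor(stats::runif(1, 0, Ld - len))
        if (!any(s < acc[, 2] + 1000 & acc[, 1] < s + len + 1000)) {
          acc <- rbind(acc, c(s, s + len))
          break
        }
      }
    }
    scale <- Lr / Ld
    for (i in seq_len(nrow(acc))) {
      s <- acc[i, 1]; e <- acc[i, 2]
      rs <- round(s * scale)
      re <- min(rs + (e - s), Lr)
      Biostrings::subseq(rseqs[[ch]], rs + 1, re) <-
        Biostrings::subseq(donor@sequences[[ch]], s + 1, s + (re - rs))
    }
    tracts[[ch]] <- data.frame(chrom = ch, start = acc[, 1], end = acc[, 2])
  }
  gen <- Genome(speciesLabel(recipient), sequences = rseqs,
                sexChrom = sexChromosome(recipient),
                markers = markerLoci(recipient))
  list(genome = gen, tracts = do.call(rbind, tracts))
}

#' Record a dominant marker insertion on a genome
#'
#' The marker (e.g. an integrated GFP cassette) is recorded as a
#' zero-footprint locus: coordinates of the genome are unchanged, and
#' carriers are treated as always detectable downstream (dominant, visible
#' semantics).
#'
#' @param genome a [Genome-class].
#' @param locus a [MarkerLocus-class].
#' @param cassetteLengthBp cassette length recorded on the locus.
#' @return the genome with the marker recorded.
#' @export
insertMarker <- function(genome, locus, cassetteLengthBp = 5000) {
  stopifnot(is(genome, "Genome"), is(locus, "MarkerLocus"))
  if (grepl("^contam", locus@chrom))
    stop("marker locus on a contaminant contig: ", locus@chrom)
  if (!locus@chrom %in% chromNames(genome))
    stop("no chromosome '", locus@chrom, "' in genome")
  if (locus@position >= chromLengths(genome)[[locus@chrom]])
    stop("marker position beyond end of chromosome ", locus@chrom)
  locus@cassetteLength <- as.numeric(cassetteLengthBp)
  genome@markers <- c(genome@markers, list(locus))
  genome
}
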
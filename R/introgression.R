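#' Construct a CrossScheme
#'
#' @param linkage \code{"autosomal"} or \code{"x_linked"}.
#' @param largeXEffect restrict X-linked carrier selection to females
#'   (hybrid males inviable/sterile).
#' @param generations marker-selected backcross generations to run.
#' @param broodSize offspring per cross before the brood is exhausted.
#' @param crossoverModel \code{"obligate_single"} or \code{"poisson"}.
#' @param seed integer seed owning all randomness of the run.
#' @param retries broods retried per generation.
#' @return a [CrossScheme-class].
#' @export
crossScheme <- function(linkage = c("autosomal", "x_linked"),
                        largeXEffect = FALSE, generations = 8,
                        broodSize = 20,
                        crossoverModel = c("obligate_single", "poisson"),
                        seed = 1, retries = 10) {
  new("CrossScheme", linkage = match.arg(linkage),
      largeXEffect = largeXEffect, generations = generations,
      broodSize = broodSize, crossoverModel = match.arg(crossoverModel),
      seed = seed, retries = retries)
}

#' @export
setMethod("show", "CrossScheme", function(object) {
  cat(sprintf(paste0("CrossScheme: %s marker%s, %g generations, brood %g, ",
                     "%s crossovers, seed %g\n"),
              object@linkage,
              if (object@largeXEffect) " (large-X effect)" else "",
              object@generations, object@broodSize, object@crossoverModel,
              object@seed))
})

#' @export
setMethod("show", "Individual", function(object) {
  nseg <- sum(vapply(object@haplotypes,
                     function(hs) sum(vapply(hs, function(h)
                       sum(h$origins == "donor"), integer(1))), integer(1)))
  cat(sprintf("Individual: %s, generation %g, %s carrier, %d donor segment(s)\n",
              object@sex, object@generation,
              if (markerCarrier(object)) "marker" else "non-carrier", nseg))
})

## Order-invariant per-draw seeds: mixes the scheme seed with generation,
## trial and a purpose string (chromosome name or "sex"), so that
## reordering chromosomes cannot change any chromosome's stream.
.hashString <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483629
  h
}

.mixSeed <- function(seed, gen, trial, what) {
  v <- (seed * 2654435761 + gen * 40503 + trial * 69621 + .hashString(what)) %%
    2147483647
  as.integer(v)
}

#' Construct the F1 hybrid female
#'
#' Marker-carrying donor males are crossed to recipient females; F1 hybrid
#' males are inviable or sterile, so the F1 carrier is female and
#' heterozygous donor/recipient genome-wide: each autosome pairs one
#' all-donor with one all-recipient haplotype, and the X pairs the paternal
#' donor X with a maternal recipient X. Generation 1.
#'
#' @param donor,recipient [Genome-class] objects (coordinate-only is fine);
#'   chromosome lengths are taken from the donor.
#' @param marker the [MarkerLocus-class] carried by the donor parent
#'   (homozygous/hemizygous).
#' @param scheme a [CrossScheme-class].
#' @return an [Individual-class].
#' @export
makeF1 <- function(donor, recipient, marker, scheme = crossScheme()) {
  stopifnot(is(donor, "Genome"), is(marker, "MarkerLocus"))
  if (!marker@chrom %in% chromNames(donor))
    stop("marker chromosome not in donor genome")
  haps <- lapply(chromNames(donor), function(ch) {
    L <- chromLengths(donor)[[ch]]
    list(newHaplotype(L, "donor"), newHaplotype(L, "recipient"))
  })
  names(haps) <- chromNames(donor)
  new("Individual", sex = "female", haplotypes = haps, marker = marker,
      generation = 1)
}

#' Does this individual carry the dominant marker?
#'
#' @param ind an [Individual-class].
#' @return TRUE iff some haplotype has a donor segment containing the
#'   marker position.
#' @export
markerCarrier <- function(ind) {
  m <- ind@marker
  hs <- ind@haplotypes[[m@chrom]]
  if (is.null(hs)) return(FALSE)
  any(vapply(hs, function(h) originAt(h, m@position) == "donor", logical(1)))
}

#' Meiosis kernel: one transmitted haplotype from a bivalent
#'
#' Under \code{"obligate_single"} exactly one crossover forms per bivalent,
#' uniform in genetic coordinates; the transmitted chromatid is one of the
#' four products, so it is recombinant with probability 1/2 and otherwise a
#' parental haplotype chosen equiprobably (complete interference, the
#' Caenorhabditis regime). Under \code{"poisson"} the transmitted chromatid
#' carries Poisson(map length in Morgans) crossovers, i.i.d. uniform in
#' genetic coordinates, starting strand equiprobable. Crossover positions
#' are mapped to physical coordinates through the genetic map; the result is
#' canonical merged.
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param hapA,hapB the parental haplotypes.
#' @param map a [GeneticMap-class].
#' @param chrom chromosome name.
#' @param model crossover model.
#' @return a gamete haplotype.
#' @export
meioseHaplotypes <- function(hapA, hapB, map, chrom,
                             model = c("obligate_single", "poisson")) {
  model <- match.arg(model)
  Lc <- mapLengthCM(map, chrom)
  if (model == "obligate_single") {
    u <- stats::runif(2)
    if (u[2] < 0.5) {  # parental chromatid transmitted
      return(if (u[2] < 0.25) hapA else hapB)
    }
    cut <- geneticToPhysical(map, chrom, u[1] * Lc)
    .recombineHaplotypes(hapA, hapB, cut,
                         startWith = if (u[2] < 0.75) 1L else 2L)
  } else {
    n <- stats::rpois(1, Lc / 100)
    startWith <- if (stats::runif(1) < 0.5) 1L else 2L
    if (n == 0L)
      return(if (startWith == 1L) hapA else hapB)
    cuts <- geneticToPhysical(map, chrom, sort(stats::runif(n) * Lc))
    .recombineHaplotypes(hapA, hapB, cuts, startWith = startWith)
  }
}

#' Meiosis for one chromosome of an individual
#'
#' Hemizygous chromosomes (the male X) are transmitted without
#' recombination.
#'
#' @param parent an [Individual-class].
#' @param chrom chromosome name.
#' @param map a [GeneticMap-class].
#' @param model crossover model.
#' @param seed optional seed applied before drawing.
#' @return a gamete haplotype.
#' @export
meiosis <- function(parent, chrom, map,
                    model = c("obligate_single", "poisson"), seed = NULL) {
  hs <- parent@haplotypes[[chrom]]
  if (is.null(hs)) stop("individual has no chromosome '", chrom, "'")
  if (!is.null(seed)) set.seed(seed)
  if (length(hs) == 1L) return(hs[[1]])
  meioseHaplotypes(hs[[1]], hs[[2]], map, chrom, model = match.arg(model))
}

## A pure-recipient mate with the carrier's chromosome lengths.
.pureRecipient <- function(carrier, sex) {
  chroms <- names(carrier@haplotypes)
  xchr <- .xChromOf(carrier)
  haps <- lapply(chroms, function(ch) {
    L <- .chromLenOf(carrier, ch)
    if (!is.na(xchr) && ch == xchr && sex == "male")
      list(newHaplotype(L, "recipient"))
    else
      list(newHaplotype(L, "recipient"), newHaplotype(L, "recipient"))
  })
  names(haps) <- chroms
  new("Individual", sex = sex, haplotypes = haps, marker = carrier@marker,
      generation = 0)
}

.chromLenOf <- function(ind, ch) {
  h <- ind@haplotypes[[ch]][[1]]
  h$ends[length(h$ends)]
}

## The X is the chromosome that can be hemizygous; identified by name.
.xChromOf <- function(ind) {
  nm <- names(ind@haplotypes)
  if ("X" %in% nm) "X" else NA_character_
}

#' One marker-selected backcross
#'
#' Crosses the carrier to a pure recipient of the opposite sex and returns
#' the first marker-positive offspring of the sex the scheme requires
#' (autosomal schemes accept either sex; X-linked schemes with a large-X
#' effect accept females only; X-linked schemes without it alternate carrier
#' sex with generation parity, which is what the opposite crossing
#' directions achieve). Offspring sex follows X0 determination: daughters
#' receive the father's X, sons carry only the maternal X. Generation is
#' incremented. When no acceptable offspring appears within the brood a
#' brood-exhausted error (condition class \code{introMap_brood_exhausted})
#' is signalled; [runIntrogression()] retries fresh broods.
#'
#' @param carrier a marker-positive [Individual-class].
#' @param scheme a [CrossScheme-class].
#' @param map a [GeneticMap-class].
#' @param trialOffset offsets the per-trial seed stream (used for retries).
#' @return the next-generation carrier [Individual-class].
#' @export
backcrossOnce <- function(carrier, scheme, map, trialOffset = 0) {
  if (!markerCarrier(carrier))
    stop(structure(class = c("introMap_brood_exhausted", "error", "condition"),
                   list(message = "carrier is not marker-positive: no marker-positive offspring possible",
                        call = sys.call(-1))))
  gen <- carrier@generation
  nextGen <- gen + 1
  requiredSex <- if (scheme@linkage == "x_linked") {
    if (scheme@largeXEffect) "female"
    else if (nextGen %% 2 == 0) "male" else "female"
  } else NA_character_
  mateSex <- if (carrier@sex == "female") "male" else "female"
  mate <- .pureRecipient(carrier, mateSex)
  mother <- if (carrier@sex == "female") carrier else mate
  father <- if (carrier@sex == "female") mate else carrier
  chroms <- names(carrier@haplotypes)
  xchr <- .xChromOf(carrier)
  for (trial in seq_len(scheme@broodSize)) {
    tix <- trial + trialOffset
    set.seed(.mixSeed(scheme@seed, nextGen, tix, "sex"))
    isFemale <- stats::runif(1) < 0.5  # paternal X-bearing vs nullo-X sperm
    sex <- if (isFemale) "female" else "male"
    if (!is.na(requiredSex) && sex != requiredSex) next
    haps <- vector("list", length(chroms))
    names(haps) <- chroms
    for (ch in chroms) {
      set.seed(.mixSeed(scheme@seed, nextGen, tix, ch))
      if (!is.na(xchr) && ch == xchr) {
        mGam <- meiosis(mother, ch, map, scheme@crossoverModel)
        if (isFemale) {
          pGam <- father@haplotypes[[ch]][[1]]  # intact paternal X
          haps[[ch]] <- list(mGam, pGam)
        } else {
          haps[[ch]] <- list(mGam)  # X0 male
        }
      } else {
        haps[[ch]] <- list(meiosis(mother, ch, map, scheme@crossoverModel),
                           meiosis(father, ch, map, scheme@crossoverModel))
      }
    }
    child <- new("Individual", sex = sex, haplotypes = haps,
                 marker = carrier@marker, generation = nextGen)
    if (markerCarrier(child)) return(child)
  }
  stop(structure(class = c("introMap_brood_exhausted", "error", "condition"),
                 list(message = sprintf(
                   "no marker-positive %s offspring in a brood of %g",
                   if (is.na(requiredSex)) "" else requiredSex,
                   scheme@broodSize), call = sys.call(-1))))
}

#' Run a full marker-selected introgression
#'
#' Builds the F1 and iterates [backcrossOnce()] for the scheme's number of
#' generations, retrying exhausted broods up to the scheme's retry budget.
#' Deterministic under a fixed scheme seed, independent of chromosome
#' ordering.
#'
#' @param donor,recipient [Genome-class] objects (coordinate-only works).
#' @param marker the [MarkerLocus-class] being introgressed.
#' @param scheme a [CrossScheme-class].
#' @param map a [GeneticMap-class].
#' @return list with \code{trajectory} (list of [Individual-class], F1
#'   first) and \code{stats} (data.frame: generation, marker_linked_bp,
#'   total_donor_bp, n_donor_segments).
#' @export
runIntrogression <- function(donor, recipient, marker, scheme, map) {
  carrier <- makeF1(donor, recipient, marker, scheme)
  traj <- list(carrier)
  for (g in seq_len(scheme@generations)) {
    child <- NULL
    for (attempt in seq_len(scheme@retries)) {
      child <- tryCatch(
        backcrossOnce(carrier, scheme, map,
                      trialOffset = (attempt - 1) * scheme@broodSize),
        introMap_brood_exhausted = function(e) NULL)
      if (!is.null(child)) break
    }
    if (is.null(child))
      stop(structure(class = c("introMap_brood_exhausted", "error", "condition"),
                     list(message = sprintf(
                       "generation %d: brood exhausted after %g retries",
                       g + 1, scheme@retries), call = sys.call(-1))))
    carrier <- child
    traj[[length(traj) + 1L]] <- carrier
  }
  stats <- do.call(rbind, lapply(traj, function(ind) {
    s <- segmentStats(ind)
    data.frame(generation = ind@generation,
               marker_linked_bp = if (is.na(s$markerLinkedBp)) NA_real_ else s$markerLinkedBp,
               total_donor_bp = s$totalDonorBp,
               n_donor_segments = sum(s$donorSegments))
  }))
  list(trajectory = traj, stats = stats)
}

#' Donor-segment statistics of an individual
#'
#' @param ind an [Individual-class].
#' @return list with \code{markerLinkedBp} (physical length of the donor
#'   segment containing the marker on the carrier haplotype; NA for
#'   marker-negative individuals), \code{totalDonorBp} (donor bp summed over
#'   all haplotypes) and \code{donorSegments} (named count of donor segments
#'   per chromosome, both haplotypes).
#' @export
segmentStats <- function(ind) {
  m <- ind@marker
  linked <- NA_real_
  hs <- ind@haplotypes[[m@chrom]]
  if (!is.null(hs)) {
    for (h in hs) {
      seg <- .segmentAt(h, m@position, "donor")
      if (!is.null(seg)) { linked <- seg[2] - seg[1]; break }
    }
  }
  total <- 0
  counts <- integer(length(ind@haplotypes))
  names(counts) <- names(ind@haplotypes)
  for (ch in names(ind@haplotypes)) {
    for (h in ind@haplotypes[[ch]]) {
      total <- total + .donorBp(h)
      counts[ch] <- counts[ch] + sum(h$origins == "donor")
    }
  }
  list(markerLinkedBp = linked, totalDonorBp = total, donorSegments = counts)
}

#' Expected retained donor length on one flank
#'
#' Closed-form oracle for the Poisson crossover model with marker-side
#' selection: after \code{t} marker-selected backcross meioses at crossover
#' rate 1 per Morgan per meiosis, the retained donor length on a flank of
#' genetic extent \code{flank} Morgans is min(flank, Exp(t)) in
#' distribution, with expectation (1 - exp(-t * flank)) / t Morgans.
#'
#' @param t number of marker-selected meioses (>= 1).
#' @param flank genetic extent of the flank in Morgans (>= 0).
#' @return expected retained length in Morgans (vectorized).
#' @export
expectedFlankLength <- function(t, flank) {
  stopifnot(all(t >= 1), all(flank >= 0))
  (1 - exp(-t * flank)) / t
}

#' Build a synthetic introgression carrier
#'
#' An individual that is pure recipient except for one heterozygous donor
#' segment containing the marker - the canonical product of repeated
#' marker-selected backcrossing, useful for deterministic genotyping
#' demonstrations.
#'
#' @param genome a [Genome-class] giving the karyotype.
#' @param marker a [MarkerLocus-class] inside the segment.
#' @param segmentStart,segmentEnd 0-based half-open bounds of the donor
#'   segment.
#' @param sex individual sex.
#' @param generation generation label.
#' @return an [Individual-class].
#' @export
syntheticCarrier <- function(genome, marker, segmentStart, segmentEnd,
                             sex = "female", generation = 8) {
  stopifnot(segmentStart < segmentEnd,
            marker@position >= segmentStart, marker@position < segmentEnd)
  chroms <- chromNames(genome)
  xchr <- sexChromosome(genome)
  haps <- lapply(chroms, function(ch) {
    L <- chromLengths(genome)[[ch]]
    if (ch == marker@chrom) {
      ends <- unique(c(segmentStart, segmentEnd, L))
      ends <- ends[ends > 0]
      origins <- character(length(ends))
      origins[ends == segmentEnd] <- "donor"
      origins[ends != segmentEnd] <- "recipient"
      carrierHap <- .canonicalHap(ends, origins)
      if (!is.na(xchr) && ch == xchr && sex == "male") list(carrierHap)
      else list(carrierHap, newHaplotype(L, "recipient"))
    } else if (!is.na(xchr) && ch == xchr && sex == "male") {
      list(newHaplotype(L, "recipient"))
    } else {
      list(newHaplotype(L, "recipient"), newHaplotype(L, "recipient"))
    }
  })
  names(haps) <- chroms
  new("Individual", sex = sex, haplotypes = haps, marker = marker,
      generation = generation)
}
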
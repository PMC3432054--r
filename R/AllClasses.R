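#' @import methods
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Genome: a set of named chromosomes with optional sequence
#'
#' A lightweight container for one genome of the species pair. Sequences are
#' optional: most of the simulator and the coordinate-mode genotyper only need
#' chromosome names and lengths ("coordinate-only mode"), while the primer
#' designer and the sequence-mode genotyper require sequence.
#'
#' @slot species species label, e.g. \code{"donor"} or \code{"recipient"}.
#' @slot sequences a [Biostrings::DNAStringSet] named by chromosome, or an
#'   empty set in coordinate-only mode.
#' @slot lengths named numeric vector of chromosome lengths in bp.
#' @slot sexChrom name of the X chromosome, or \code{NA_character_}.
#' @slot markers list of [MarkerLocus-class] objects recorded on this genome.
#'
#' @seealso [Genome()], [readGenome()], [defaultKaryotype()]
#' @exportClass Genome
setClass("Genome",
  representation(
    species   = "character",
    sequences = "DNAStringSet",
    lengths   = "numeric",
    sexChrom  = "character",
    markers   = "list"
  )
)

setValidity("Genome", function(object) {
  msg <- NULL
  nm <- names(object@lengths)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "chromosome lengths must be named")
  if (anyDuplicated(nm))
    msg <- c(msg, "chromosome names must be unique")
  if (any(object@lengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(object@sequences) > 0L) {
    if (!identical(names(object@sequences), nm))
      msg <- c(msg, "sequence names must match chromosome names")
    else if (!all(Biostrings::width(object@sequences) == unname(object@lengths)))
      msg <- c(msg, "sequence widths must equal declared lengths")
  }
  sx <- object@sexChrom
  if (length(sx) != 1L)
    msg <- c(msg, "sexChrom must be a single name or NA")
  else if (!is.na(sx) && !(sx %in% nm))
    msg <- c(msg, sprintf("sex chromosome '%s' is not a chromosome of this genome", sx))
  if (length(object@markers) &&
      !all(vapply(object@markers, is, logical(1), class2 = "MarkerLocus")))
    msg <- c(msg, "markers must be MarkerLocus objects")
  if (is.null(msg)) TRUE else msg
})

#' Piecewise-linear genetic map
#'
#' Anchor points (physical bp, genetic cM) per chromosome; positions between
#' anchors are interpolated linearly. The first anchor of every chromosome is
#' (0, 0), both coordinates are strictly increasing, and the last physical
#' anchor is the chromosome length. No Haldane/Kosambi map function is
#' applied: crossovers are simulated directly in genetic coordinates.
#'
#' @slot anchors data.frame with columns \code{chrom}, \code{physical_bp}
#'   (0-based bp), \code{genetic_cM}.
#' @seealso [armWeightedMap()], [physicalToGenetic()], [geneticToPhysical()]
#' @exportClass GeneticMap
setClass("GeneticMap",
         representation(anchors = "data.frame", cache = "environment"))

setValidity("GeneticMap", function(object) {
  a <- object@anchors
  need <- c("chrom", "physical_bp", "genetic_cM")
  if (!all(need %in% names(a)))
    return(sprintf("anchors must have columns %s", paste(need, collapse = ", ")))
  for (ch in unique(a$chrom)) {
    s <- a[a$chrom == ch, , drop = FALSE]
    if (nrow(s) < 2L)
      return(sprintf("chromosome '%s' needs at least two anchors", ch))
    if (s$physical_bp[1] != 0 || s$genetic_cM[1] != 0)
      return(sprintf("chromosome '%s': first anchor must be (0, 0)", ch))
    if (any(diff(s$physical_bp) <= 0) || any(diff(s$genetic_cM) <= 0))
      return(sprintf("chromosome '%s': anchors must be strictly increasing", ch))
  }
  TRUE
})

#' A dominant marker locus
#'
#' Position of a dominant, visible marker (e.g. an integrated pharyngeal GFP
#' cassette) on a genome, in the shared donor coordinate system. Carriers are
#' always detectable, so heterozygotes can be selected every generation.
#'
#' @slot chrom chromosome name.
#' @slot position 0-based physical position in bp.
#' @slot label marker label, e.g. \code{"GFP"}.
#' @slot cassetteLength length of the inserted cassette in bp (annotation
#'   only; the cassette has zero footprint on coordinates).
#' @exportClass MarkerLocus
setClass("MarkerLocus",
  representation(chrom = "character", position = "numeric",
                 label = "character", cassetteLength = "numeric"),
  prototype(label = "GFP", cassetteLength = 0)
)

setValidity("MarkerLocus", function(object) {
  if (length(object@chrom) != 1L || length(object@position) != 1L)
    return("chrom and position must be scalars")
  if (object@position < 0) return("position must be >= 0")
  TRUE
})

#' Backcross introgression scheme
#'
#' Configuration of the repeated-backcross design: whether the marker is
#' autosomal or X-linked, whether a large-X effect restricts carrier choice to
#' females, how many marker-selected backcross generations to run, the brood
#' size per cross, and the meiotic crossover model.
#'
#' @slot linkage \code{"autosomal"} or \code{"x_linked"}.
#' @slot largeXEffect if TRUE (X-linked schemes), only female carriers are
#'   selected; otherwise carrier sex alternates with generation parity.
#' @slot generations number of marker-selected backcross generations.
#' @slot broodSize offspring examined per cross before declaring the brood
#'   exhausted.
#' @slot crossoverModel \code{"obligate_single"} (one crossover per bivalent,
#'   complete interference, the Caenorhabditis default) or \code{"poisson"}
#'   (crossovers on the transmitted chromatid at 1 per Morgan).
#' @slot seed integer seed owning all randomness of a run.
#' @slot retries broods retried per generation before giving up.
#' @seealso [crossScheme()], [runIntrogression()]
#' @exportClass CrossScheme
setClass("CrossScheme",
  representation(linkage = "character", largeXEffect = "logical",
                 generations = "numeric", broodSize = "numeric",
                 crossoverModel = "character", seed = "numeric",
                 retries = "numeric")
)

setValidity("CrossScheme", function(object) {
  if (!object@linkage %in% c("autosomal", "x_linked"))
    return("linkage must be 'autosomal' or 'x_linked'")
  if (!object@crossoverModel %in% c("obligate_single", "poisson"))
    return("crossoverModel must be 'obligate_single' or 'poisson'")
  if (object@generations < 1) return("generations must be >= 1")
  if (object@broodSize < 1) return("broodSize must be >= 1")
  if (object@retries < 1) return("retries must be >= 1")
  TRUE
})

#' A (possibly hybrid) individual with junction/segment ancestry
#'
#' Haplotypes are ordered donor/recipient ancestry segments tiling each
#' chromosome (junction representation). Females carry two X haplotypes,
#' males one (X0 sex determination).
#'
#' @slot sex \code{"female"} or \code{"male"}.
#' @slot haplotypes named list (by chromosome) of lists of haplotypes; each
#'   haplotype is a list with numeric \code{ends} (segment end coordinates,
#'   0-based half-open, last = chromosome length) and character
#'   \code{origins} (\code{"donor"}/\code{"recipient"}), in canonical merged
#'   form. See [haplotypeSegments()].
#' @slot marker the [MarkerLocus-class] tracked through the cross.
#' @slot generation marker-selected generation counter (F1 = 1).
#' @exportClass Individual
setClass("Individual",
  representation(sex = "character", haplotypes = "list",
                 marker = "MarkerLocus", generation = "numeric")
)

setValidity("Individual", function(object) {
  if (!object@sex %in% c("female", "male"))
    return("sex must be 'female' or 'male'")
  if (is.null(names(object@haplotypes)))
    return("haplotypes must be named by chromosome")
  TRUE
})
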
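#' Construct a Genome
#'
#' @param species species label.
#' @param sequences a named [Biostrings::DNAStringSet], named character vector
#'   of sequences, or \code{NULL} for coordinate-only mode.
#' @param lengths named numeric vector of chromosome lengths; derived from
#'   \code{sequences} when those are given.
#' @param sexChrom name of the X chromosome (\code{NA} for none).
#' @param markers list of [MarkerLocus-class] objects.
#' @return a [Genome-class].
#' @examples
#' g <- Genome("donor", sequences = c(I = "ACGTACGT", X = "TTTTAAAA"),
#'             sexChrom = "X")
#' chromLengths(g)
#' @export
Genome <- function(species, sequences = NULL, lengths = NULL,
                   sexChrom = NA_character_, markers = list()) {
  if (is.null(sequences)) {
    sequences <- Biostrings::DNAStringSet()
    if (is.null(lengths)) stop("one of 'sequences' or 'lengths' is required")
  } else {
    if (!is(sequences, "DNAStringSet"))
      sequences <- Biostrings::DNAStringSet(sequences)
    if (is.null(lengths)) {
      lengths <- as.numeric(Biostrings::width(sequences))
      names(lengths) <- names(sequences)
    }
  }
  new("Genome", species = species, sequences = sequences,
      lengths = lengths, sexChrom = as.character(sexChrom), markers = markers)
}

#' @rdname Genome
#' @param x,object a [Genome-class].
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))

#' @rdname Genome
#' @export
setMethod("speciesLabel", "Genome", function(x) x@species)

#' @rdname Genome
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname Genome
#' @export
setMethod("chromNames", "Genome", function(x) names(x@lengths))

#' @rdname Genome
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname Genome
#' @export
setMethod("chromLengths", "Genome", function(x) x@lengths)

#' @rdname Genome
#' @export
setGeneric("sexChromosome", function(x) standardGeneric("sexChromosome"))

#' @rdname Genome
#' @export
setMethod("sexChromosome", "Genome", function(x) x@sexChrom)

#' @rdname Genome
#' @export
setGeneric("markerLoci", function(x) standardGeneric("markerLoci"))

#' @rdname Genome
#' @export
setMethod("markerLoci", "Genome", function(x) x@markers)

#' @rdname Genome
#' @export
hasSequence <- function(x) length(x@sequences) > 0L

#' @rdname Genome
#' @param chrom chromosome name.
#' @export
chromSequence <- function(x, chrom) {
  stopifnot(is(x, "Genome"))
  if (!hasSequence(x)) stop("genome '", x@species, "' is coordinate-only")
  if (!chrom %in% names(x@sequences)) stop("no chromosome '", chrom, "'")
  x@sequences[[chrom]]
}

#' @export
setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome '%s': %d chromosome(s), %.2f Mb total%s\n",
              object@species, length(object@lengths),
              sum(object@lengths) / 1e6,
              if (hasSequence(object)) "" else " (coordinate-only)"))
  sx <- object@sexChrom
  cat(sprintf("  chromosomes: %s%s\n",
              paste(names(object@lengths), collapse = ", "),
              if (!is.na(sx)) sprintf(" (X: %s)", sx) else ""))
  for (m in object@markers)
    cat(sprintf("  marker %s at %s:%.0f\n", m@label, m@chrom, m@position))
})

#' Construct a MarkerLocus
#'
#' @param chrom chromosome name.
#' @param position 0-based position in bp.
#' @param label marker label.
#' @param cassetteLength cassette length in bp (annotation only).
#' @return a [MarkerLocus-class].
#' @export
MarkerLocus <- function(chrom, position, label = "GFP", cassetteLength = 0) {
  new("MarkerLocus", chrom = chrom, position = as.numeric(position),
      label = label, cassetteLength = as.numeric(cassetteLength))
}

#' @export
setMethod("show", "MarkerLocus", function(object) {
  cat(sprintf("MarkerLocus %s at %s:%.0f\n",
              object@label, object@chrom, object@position))
})

#' Default demo karyotype
#'
#' Five autosomes (I-V) plus an X, each of the same length, mirroring the
#' chromosome-scale organisation of Caenorhabditis briggsae at a configurable
#' size. Coordinate-only (no sequence); pair with [armWeightedMap()] for the
#' arm-biased recombination landscape.
#'
#' @param chromLength chromosome length in bp (default 15 Mb).
#' @param nAutosomes number of autosomes (default 5).
#' @param species species label.
#' @return a coordinate-only [Genome-class].
#' @examples
#' defaultKaryotype()
#' @export
defaultKaryotype <- function(chromLength = 15e6, nAutosomes = 5,
                             species = "donor") {
  nm <- c(as.character(utils::as.roman(seq_len(nAutosomes))), "X")
  lens <- rep(as.numeric(chromLength), nAutosomes + 1L)
  names(lens) <- nm
  Genome(species, lengths = lens, sexChrom = "X")
}
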
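#' Read a genome from FASTA
#'
#' Headers are truncated at the first whitespace to obtain chromosome names.
#' The X chromosome is identified by a configurable name pattern.
#'
#' @param path FASTA file.
#' @param species species label for the resulting genome.
#' @param xPattern regular expression identifying the sex chromosome.
#' @return a [Genome-class] with sequences.
#' @export
readGenome <- function(path, species = basename(path),
                       xPattern = "^(chr)?X$") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA headers in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty FASTA records in ", path)
  xs <- grep(xPattern, names(seqs), value = TRUE)
  if (length(xs) > 1L)
    stop("more than one chromosome matches the X pattern: ",
         paste(xs, collapse = ", "))
  Genome(species, sequences = seqs,
         sexChrom = if (length(xs)) xs else NA_character_)
}

#' Write a genome to FASTA
#'
#' @param genome a [Genome-class] with sequences.
#' @param path output FASTA file.
#' @export
writeGenome <- function(genome, path) {
  stopifnot(is(genome, "Genome"))
  if (!hasSequence(genome)) stop("cannot write a coordinate-only genome")
  Biostrings::writeXStringSet(genome@sequences, path)
  invisible(path)
}

.KINDS <- c("exon", "intron", "intergenic", "repeat")
.GFF_TYPE <- c(exon = "exon", intron = "intron",
               intergenic = "intergenic_region", repeat. = "repeat_region")

#' Read annotation from GFF3 or BED
#'
#' Features are held as a [GenomicRanges::GRanges] with a \code{kind}
#' metadata column (exon, intron, intergenic, repeat). GFF3 is 1-based
#' closed, BED 0-based half-open; both converge on the GRanges convention at
#' this boundary. Use [featureTable()] for a 0-based half-open view.
#'
#' @param path a \code{.gff3}/\code{.gff} or \code{.bed} file.
#' @param seqlengths optional named chromosome lengths to attach.
#' @return a GRanges with a \code{kind} column.
#' @export
readAnnotation <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import.bed(path)
    kind <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
  } else {
    gr <- rtracklayer::import.gff3(path)
    kind <- as.character(gr$type)
    kind[kind == "repeat_region"] <- "repeat"
    kind[kind == "intergenic_region"] <- "intergenic"
  }
  if (!all(kind %in% .KINDS))
    stop("unknown feature kinds: ",
         paste(setdiff(unique(kind), .KINDS), collapse = ", "))
  if (any(GenomicRanges::width(gr) < 1L))
    stop("features with end <= start in ", path)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(kind = kind)
  if (!is.null(seqlengths)) {
    if (is(seqlengths, "Genome")) seqlengths <- chromLengths(seqlengths)
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- as.integer(seqlengths)
  }
  gr
}

#' Write annotation to GFF3 or BED
#'
#' @param annotation GRanges with a \code{kind} column.
#' @param path output path; format chosen by extension.
#' @export
writeAnnotation <- function(annotation, path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- annotation
    gr$name <- gr$kind
    gr$kind <- NULL
    rtracklayer::export.bed(gr, path)
  } else {
    gr <- annotation
    gr$type <- ifelse(gr$kind == "repeat", "repeat_region",
               ifelse(gr$kind == "intergenic", "intergenic_region", gr$kind))
    gr$source <- "introMap"
    gr$kind <- NULL
    rtracklayer::export.gff3(gr, path)
  }
  invisible(path)
}

#' 0-based half-open view of an annotation
#'
#' @param annotation GRanges with a \code{kind} column.
#' @return data.frame with \code{chrom}, \code{start} (0-based),
#'   \code{end} (exclusive), \code{strand}, \code{kind}.
#' @export
featureTable <- function(annotation) {
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(annotation)),
    start = GenomicRanges::start(annotation) - 1,
    end = as.numeric(GenomicRanges::end(annotation)),
    strand = as.character(GenomicRanges::strand(annotation)),
    kind = annotation$kind,
    stringsAsFactors = FALSE
  )
}

#' Intergenic complement of the gene features
#'
#' The complement of the gene spans (exons and introns) on each chromosome.
#' Together with the gene spans these partition the chromosome.
#'
#' @param annotation GRanges with a \code{kind} column and seqlengths set
#'   (or supply \code{genome}).
#' @param genome optional [Genome-class] supplying chromosome lengths.
#' @return GRanges of intergenic intervals (\code{kind = "intergenic"}).
#' @export
intergenicRegions <- function(annotation, genome = NULL) {
  gr <- annotation
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- chromNames(genome)
    GenomeInfoDb::seqlengths(gr) <- as.integer(chromLengths(genome))
  }
  if (anyNA(GenomeInfoDb::seqlengths(gr)))
    stop("seqlengths required to derive intergenic regions")
  genes <- GenomicRanges::reduce(gr[gr$kind %in% c("exon", "intron")],
                                 ignore.strand = TRUE)
  inter <- GenomicRanges::gaps(genes)
  inter <- inter[GenomicRanges::strand(inter) == "*"]
  inter$kind <- rep("intergenic", length(inter))
  inter
}

#' Read / write a genetic map as TSV
#'
#' Columns \code{chrom}, \code{physical_bp}, \code{genetic_cM}.
#'
#' @param path TSV file.
#' @return a [GeneticMap-class].
#' @export
readGeneticMap <- function(path) {
  if (!file.exists(path)) stop("genetic map file not found: ", path)
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  GeneticMap(a[c("chrom", "physical_bp", "genetic_cM")])
}

#' @rdname readGeneticMap
#' @param map a [GeneticMap-class].
#' @export
writeGeneticMap <- function(map, path) {
  utils::write.table(map@anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
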
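#' Write a complete synthetic fixture to a directory
#'
#' Generates a sister pair and writes donor/recipient FASTA, annotation
#' GFF3, an arm-weighted genetic map TSV, ground-truth shared-haplotype
#' tracts as BED (when present) and a JSON echo of the configuration
#' (including the seed).
#'
#' @param dir output directory (created if needed).
#' @param config a [divergenceConfig()].
#' @return (invisibly) list with the generated objects and file paths.
#' @export
makeFixture <- function(dir, config = divergenceConfig()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pair <- generateSisterPair(config)
  paths <- list(
    donor = file.path(dir, "donor.fasta"),
    recipient = file.path(dir, "recipient.fasta"),
    annotation = file.path(dir, "annotation.gff3"),
    map = file.path(dir, "genetic_map.tsv"),
    config = file.path(dir, "config.json"))
  writeGenome(pair$donor, paths$donor)
  writeGenome(pair$recipient, paths$recipient)
  writeAnnotation(pair$annotation, paths$annotation)
  map <- armWeightedMap(pair$donor)
  writeGeneticMap(map, paths$map)
  if (nrow(pair$sharedTracts)) {
    paths$sharedTracts <- file.path(dir, "shared_tracts.bed")
    tr <- pair$sharedTracts
    rtracklayer::export.bed(GenomicRanges::GRanges(
      tr$chrom, IRanges::IRanges(tr$start + 1, tr$end)), paths$sharedTracts)
  }
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(pair, list(map = map, paths = paths)))
}

#' Write an introgression trajectory and final-carrier segments
#'
#' @param sim result of [runIntrogression()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return (invisibly) the file paths.
#' @export
writeTrajectory <- function(sim, dir, prefix = "introgression") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, paste0(prefix, "_trajectory.tsv"))
  utils::write.table(sim$stats, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  final <- sim$trajectory[[length(sim$trajectory)]]
  segs <- list()
  for (ch in names(final@haplotypes)) {
    for (k in seq_along(final@haplotypes[[ch]])) {
      s <- haplotypeSegments(final@haplotypes[[ch]][[k]])
      s <- s[s$origin == "donor", , drop = FALSE]
      if (nrow(s))
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = ch, start = s$start, end = s$end,
          name = sprintf("h%d", k))
    }
  }
  bed <- file.path(dir, paste0(prefix, "_donor_segments.bed"))
  if (length(segs)) {
    d <- do.call(rbind, segs)
    rtracklayer::export.bed(GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(d$start + 1, d$end), name = d$name), bed)
  } else {
    file.create(bed)
  }
  invisible(list(trajectory = tsv, segments = bed))
}

#' Run the full pipeline end to end on a synthetic fixture
#'
#' Chains fixture generation, panel design, panel validation, marker
#' insertion, marker-selected introgression, hierarchical genotyping and
#' interval inference, writing every artifact plus a manifest JSON.
#' Deterministic for a fixed seed. The default problem size is a
#' demonstration scale (three chromosomes of 150 kb, five pairs per
#' chromosome).
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param config a [divergenceConfig()]; its seed is overridden by
#'   \code{seed}.
#' @param spec a [panelSpec()].
#' @param generations backcross generations to simulate.
#' @param strain strain label used in the report.
#' @return (invisibly) list with the main objects and the manifest.
#' @export
endToEnd <- function(dir, seed = 1,
                     config = divergenceConfig(nAutosomes = 2,
                                               chromLengthBp = 150e3),
                     spec = panelSpec(primersPerChromosome = 5,
                                      productSizeRange = c(150, 500)),
                     generations = 4, strain = "LINE1") {
  config$seed <- as.integer(seed)
  fx <- makeFixture(dir, config)
  design <- designPanel(fx$donor, fx$recipient, fx$annotation, fx$map, spec)
  audit <- validatePanel(design$panel, fx$donor, fx$recipient)
  panel <- audit$panel
  panelPath <- file.path(dir, "panel.tsv")
  writePanel(panel, panelPath)
  writePanel(design$log, file.path(dir, "design_log.tsv"))
  writePanelBed(panel, file.path(dir, "panel.bed"))
  markerChrom <- chromNames(fx$donor)[1]
  marker <- MarkerLocus(markerChrom,
                        round(0.125 * chromLengths(fx$donor)[[markerChrom]]))
  donorM <- insertMarker(fx$donor, marker)
  scheme <- crossScheme(generations = generations, seed = seed + 1)
  sim <- runIntrogression(donorM, fx$recipient, marker, scheme, fx$map)
  simPaths <- writeTrajectory(sim, dir)
  final <- sim$trajectory[[length(sim$trajectory)]]
  gt <- hierarchicalGenotype(final, panel)
  reportPath <- file.path(dir, "mapping_report.tsv")
  if (!is.na(gt$assignment[1])) {
    ch <- gt$assignment[1]
    pat <- gt$pattern[gt$pattern$chrom == ch, , drop = FALSE]
    interval <- inferInterval(pat, chromLengths(fx$donor)[[ch]])
    report <- intervalReport(strain, interval)
  } else {
    report <- data.frame(strain = strain, linkage_group = NA,
                         physical_position = NA, introgression_size = NA)
  }
  utils::write.table(report, reportPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    seed = seed,
    scheme_seed = seed + 1,
    files = vapply(c(unlist(fx$paths), panel = panelPath, unlist(simPaths),
                     report = reportPath), basename, character(1)),
    panel_counts = as.list(audit$counts),
    marker = sprintf("%s:%0.f", marker@chrom, marker@position),
    generations = generations,
    reactions_used = gt$reactionsUsed,
    assignment = gt$assignment)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fixture = fx, panel = panel, audit = audit, sim = sim,
                 genotype = gt, report = report, manifest = manifest))
}
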
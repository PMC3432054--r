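test_that("target layout follows the arm density weights", {
  tg <- targetPositions(15e6, 15, c(0.4, 0.2, 0.4))
  expect_equal(as.vector(table(tg$arm)[c("left", "middle", "right")]),
               c(6, 3, 6))
  expect_true(all(diff(tg$pos) > 0))
  expect_true(all(tg$pos[tg$arm == "left"] < 5e6))
  expect_true(all(tg$pos[tg$arm == "middle"] >= 5e6 &
                    tg$pos[tg$arm == "middle"] < 10e6))
  # middle third receives the fewest targets for any arm-biased weights
  tg2 <- targetPositions(9e6, 10, c(0.4, 0.2, 0.4))
  counts <- table(tg2$arm)
  expect_true(counts["middle"] <= min(counts[c("left", "right")]))
})

test_that("candidate regions avoid exons and repeats, stepping outward as needed", {
  L <- 1e5
  ann <- GenomicRanges::GRanges(
    "I", IRanges::IRanges(c(40001, 20001), c(41000, 20200)),
    strand = "*", kind = c("exon", "repeat"),
    seqinfo = GenomeInfoDb::Seqinfo("I", as.integer(L)))
  spec <- panelSpec(candidateRegionLengthBp = 600, stepBp = 1000)
  # unobstructed target: interval centred on it
  r <- selectCandidateRegion(ann, "I", 70000, spec)
  expect_equal(r$start, 70000 - 300)
  expect_equal(r$end, 70000 + 300)
  expect_equal(r$offsetSteps, 0)
  # target inside the exon: displaced to a flanking window
  r2 <- selectCandidateRegion(ann, "I", 40500, spec)
  expect_true(r2$offsetSteps != 0)
  expect_true(r2$end <= 40000 || r2$start >= 41000)
  # target on the repeat: window clears the repeat
  r3 <- selectCandidateRegion(ann, "I", 20100, spec)
  expect_true(r3$end <= 20000 || r3$start >= 20200)
  # fully exonic chromosome: region-exhausted error
  annFull <- GenomicRanges::GRanges(
    "I", IRanges::IRanges(1, L), strand = "*", kind = "exon",
    seqinfo = GenomeInfoDb::Seqinfo("I", as.integer(L)))
  expect_error(selectCandidateRegion(annFull, "I", 50000, spec),
               class = "introMap_region_exhausted")
})

test_that("primer pairs satisfy the physical constraints and are deterministic", {
  spec <- testSpec()
  # homopolymer region: constraints unsatisfiable
  expect_null(pickPrimerPair(strrep("A", 600), spec))
  # benign random region yields a compliant pair
  set.seed(31)
  region <- randomDnaString(600)
  p <- pickPrimerPair(region, spec, chrom = "I", regionStart = 1000)
  expect_false(is.null(p))
  expect_true(nchar(p$left_seq) >= 18 && nchar(p$left_seq) <= 27)
  expect_true(nchar(p$right_seq) >= 18 && nchar(p$right_seq) <= 27)
  expect_true(p$product_size >= 150 && p$product_size <= 500)
  expect_equal(p$product_size, p$right_end - p$left_start)
  expect_true(all(c(p$tm_left, p$tm_right) >= 55) &&
                all(c(p$tm_left, p$tm_right) <= 62))
  gc <- function(s) mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_true(gc(p$left_seq) >= 0.35 && gc(p$left_seq) <= 0.65)
  expect_false(grepl("A{5}|C{5}|G{5}|T{5}", p$left_seq))
  expect_false(grepl("A{5}|C{5}|G{5}|T{5}", p$right_seq))
  # the pair amplifies its own region with the declared product size
  amp <- insilicoPcrSequence(Biostrings::DNAStringSet(c(I = region)), p)
  expect_true(amp$amplified)
  expect_true(p$product_size %in% amp$products$size)
  # determinism
  expect_identical(p, pickPrimerPair(region, spec, chrom = "I",
                                     regionStart = 1000))
})

test_that("primer Tm is strand-symmetric and in a plausible range", {
  set.seed(32)
  s <- vapply(1:20, function(i) randomDnaString(20), character(1))
  expect_equal(primerTm(s), primerTm(vapply(s, revcomp, character(1))),
               tolerance = 1e-9)
  expect_true(all(primerTm(s) > 30 & primerTm(s) < 80))
})

test_that("designed panels pass their own specificity audits", {
  pair <- testPair()
  fix <- testPanel()
  panel <- fix$panel
  # requested pair count per chromosome
  expect_equal(unname(table(panel$chrom)[chromNames(pair$donor)]),
               rep(5L, 3), ignore_attr = TRUE)
  # recorded audit fields respect the design cutoffs
  expect_true(all(panel$max_offtarget_score <= 50))
  expect_true(all(panel$max_three_prime_match <= 8))
  # every retained pair amplifies the donor and not the recipient
  expect_true(all(panel$status == "retained"))
  expect_true(all(panel$amplifies_donor))
  expect_false(any(panel$amplifies_recipient))
  # rejections are logged with a cause
  expect_true(all(fix$design$log$stage %in%
                    c("region", "specificity", "primer", "three_prime",
                      "exhausted")))
})

test_that("panel design is invariant to chromosome processing order", {
  cfg <- divergenceConfig(seed = 11, nAutosomes = 1, chromLengthBp = 8e4)
  pair <- generateSisterPair(cfg)
  spec <- panelSpec(primersPerChromosome = 3, productSizeRange = c(150, 400))
  fwd <- designPanel(pair$donor, pair$recipient, pair$annotation,
                     spec = spec)$panel
  rev1 <- local({
    g <- pair$donor
    ord <- rev(chromNames(g))
    donorR <- Genome("donor", sequences = g@sequences[ord], sexChrom = "X")
    designPanel(donorR, pair$recipient, pair$annotation, spec = spec)$panel
  })
  cols <- c("id", "chrom", "left_start", "right_end", "left_seq", "right_seq")
  expect_equal(fwd[order(fwd$id), cols], rev1[order(rev1$id), cols],
               ignore_attr = TRUE)
})

test_that("validate_panel marks every pair discarded when recipient equals donor", {
  pair <- testPair()
  panel <- testPanel()$panel
  audit <- validatePanel(panel, pair$donor, pair$donor)
  expect_equal(unname(audit$counts["retained"]), 0L)
  expect_true(all(audit$panel$status == "discarded"))
  # audit is deterministic
  audit2 <- validatePanel(panel, pair$donor, pair$donor)
  expect_identical(audit$panel$status, audit2$panel$status)
})

test_that("spacing statistics follow the layout arithmetic", {
  panel <- data.frame(id = paste0("I_", 1:3), chrom = "I",
                      left_start = c(1e6, 2e6, 3e6) - 250,
                      right_end = c(1e6, 2e6, 3e6) + 250,
                      status = "retained")
  st <- panelSpacingStats(panel)
  expect_equal(st$perChromosome$mean_gap, 1e6)
  expect_equal(st$globalMeanGap, 1e6)
  # a single-pair chromosome is omitted with a warning
  panel2 <- rbind(panel, data.frame(id = "II_1", chrom = "II",
                                    left_start = 5e6, right_end = 5e6 + 500,
                                    status = "retained"))
  expect_warning(st2 <- panelSpacingStats(panel2), "fewer than 2")
  expect_equal(st2$perChromosome$chrom, "I")
  # fixture panel spacing close to chromLength / primersPerChromosome
  st3 <- panelSpacingStats(testPanel()$panel)
  expect_lt(abs(st3$globalMeanGap - 150e3 / 5), 0.2 * 150e3 / 5)
})

test_that("panel TSV and BED writers round-trip and cover both primers", {
  panel <- testPanel()$panel
  tsv <- tempfile(fileext = ".tsv")
  writePanel(panel, tsv)
  back <- readPanel(tsv)
  expect_equal(back$id, panel$id)
  expect_equal(back$left_start, panel$left_start)
  expect_equal(back$left_seq, panel$left_seq)
  bed <- tempfile(fileext = ".bed")
  writePanelBed(panel, bed)
  sites <- rtracklayer::import.bed(bed)
  expect_length(sites, 2 * nrow(panel))
})
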
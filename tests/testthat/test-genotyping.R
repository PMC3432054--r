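test_that("coordinate-mode PCR requires one donor segment spanning both primers", {
  g <- defaultKaryotype(chromLength = 15e6, nAutosomes = 5)
  panel <- coordinatePanel(g, primersPerChromosome = 15, xPrimers = 13)
  marker <- MarkerLocus("II", 1.875e6)
  # donor throughout the chromosome: every pair on II is positive
  full <- syntheticCarrier(g, marker, 0, 15e6)
  callsII <- vapply(which(panel$chrom == "II"), function(i)
    insilicoPcrCoordinate(full, panel[i, ]), logical(1))
  expect_true(all(callsII))
  # pure recipient chromosome: every pair negative
  none <- syntheticCarrier(g, marker, 1.8e6, 1.9e6)
  none@haplotypes[["II"]][[1]] <- newHaplotype(15e6, "recipient")
  callsNone <- vapply(which(panel$chrom == "II"), function(i)
    insilicoPcrCoordinate(none, panel[i, ]), logical(1))
  expect_false(any(callsNone))
  # a segment covering the left primer but ending between the primers fails
  p <- panel[panel$chrom == "II", ][3, ]
  mid <- (p$left_start + p$right_end) / 2
  m2 <- MarkerLocus("II", p$left_start)
  split <- syntheticCarrier(g, m2, p$left_start - 100, mid)
  expect_false(insilicoPcrCoordinate(split, p))
  # extending past the right end turns the call positive
  whole <- syntheticCarrier(g, m2, p$left_start - 100, p$right_end + 100)
  expect_true(insilicoPcrCoordinate(whole, p))
})

test_that("sequence-mode binding honours the 3' core and mismatch budget", {
  set.seed(51)
  left <- randomDnaString(20)
  rightPlus <- randomDnaString(20)
  insert <- randomDnaString(260)
  template <- paste0(randomDnaString(100), left, insert, rightPlus,
                     randomDnaString(100))
  pair <- data.frame(chrom = "I", left_seq = left,
                     right_seq = revcomp(rightPlus),
                     left_start = 100, right_end = 400)
  tset <- Biostrings::DNAStringSet(c(I = template))
  res <- insilicoPcrSequence(tset, pair)
  expect_true(res$amplified)
  expect_equal(res$products$size, 20 + 260 + 20)
  # two mismatches outside the 3' core are tolerated
  mutate_at <- function(s, i) {
    v <- strsplit(s, "")[[1]]
    v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  left2 <- mutate_at(mutate_at(left, 1), 3)
  expect_true(insilicoPcrSequence(tset, transform(pair, left_seq = left2))$amplified)
  # three mismatches are not
  left3 <- mutate_at(left2, 5)
  expect_false(insilicoPcrSequence(tset, transform(pair, left_seq = left3))$amplified)
  # one mismatch inside the 15-base 3' core kills binding
  leftCore <- mutate_at(left, 15)
  expect_false(insilicoPcrSequence(tset, transform(pair, left_seq = leftCore))$amplified)
  # products beyond the size ceiling are not called
  expect_false(insilicoPcrSequence(tset, pair, maxProductBp = 250)$amplified)
})

test_that("sequence and coordinate modes agree on rendered individuals", {
  pair <- noIndelPair()
  panel <- noIndelPanel()
  keep <- panel[panel$status == "retained", , drop = FALSE]
  expect_gt(nrow(keep), 3)
  g <- pair$donor
  inds <- list(
    makeF1(g, pair$recipient, MarkerLocus("I", 3e4)),
    syntheticCarrier(g, MarkerLocus("I", 3e4), 2e4, 7e4),
    syntheticCarrier(g, MarkerLocus("X", 6e4), 5e4, 9e4)
  )
  for (ind in inds) {
    rendered <- renderIndividualGenome(ind, pair$donor, pair$recipient)
    for (i in seq_len(nrow(keep))) {
      coord <- insilicoPcrCoordinate(ind, keep[i, ])
      seqm <- insilicoPcrSequence(rendered, keep[i, ])$amplified
      expect_equal(seqm, coord,
                   info = sprintf("pair %s", keep$id[i]))
    }
  }
})

test_that("hierarchical genotyping uses the economical reaction counts", {
  g <- defaultKaryotype(chromLength = 15e6, nAutosomes = 5)
  panel <- coordinatePanel(g, primersPerChromosome = 15, xPrimers = 13)
  marker <- MarkerLocus("II", 1.875e6)
  ind <- syntheticCarrier(g, marker, 0.8e6, 3.9e6)
  gt <- hierarchicalGenotype(ind, panel)
  expect_equal(gt$assignment, "II")
  expect_equal(gt$reactionsUsed, 27)  # 15 + (15 - 3)
  expect_false(gt$multiChromosome)
  expect_equal(nrow(gt$pattern), 15)
  # known X linkage runs only the X panel
  xind <- syntheticCarrier(g, MarkerLocus("X", 5e6), 4e6, 7e6)
  gtx <- hierarchicalGenotype(xind, panel, xLinkedKnown = TRUE)
  expect_equal(gtx$assignment, "X")
  expect_equal(gtx$reactionsUsed, 13)
  # unknown X linkage is caught by the fallback after 15 + 13 reactions
  gtx2 <- hierarchicalGenotype(xind, panel)
  expect_equal(gtx2$assignment, "X")
  expect_equal(gtx2$reactionsUsed, 28)
  # marker-negative individual stays unassigned
  neg <- syntheticCarrier(g, marker, 1.8e6, 1.9e6)
  neg@haplotypes[["II"]][[1]] <- newHaplotype(15e6, "recipient")
  gtn <- hierarchicalGenotype(neg, panel)
  expect_true(is.na(gtn$assignment))
  # segments on two autosomes raise the multi-chromosome flag
  multi <- syntheticCarrier(g, marker, 0.8e6, 3.9e6)
  multi@haplotypes[["IV"]][[1]] <- haplotypeFromSegments(
    c(0, 6e6, 9e6), c(6e6, 9e6, 15e6),
    c("recipient", "donor", "recipient"))
  gtm <- hierarchicalGenotype(multi, panel)
  expect_true(gtm$multiChromosome)
  expect_setequal(gtm$assignment, c("II", "IV"))
})

test_that("interval inference reproduces the bracketing arithmetic", {
  pat <- data.frame(chrom = "I",
                    pos = c(1.5e6, 2.1e6, 3.0e6, 3.6e6),
                    call = c(FALSE, TRUE, TRUE, FALSE))
  iv <- inferInterval(pat, 15e6)
  expect_equal(iv$inner_start, 2.1e6)
  expect_equal(iv$inner_end, 3.0e6)
  expect_equal(iv$size_bp, 0.9e6)
  expect_equal(iv$outer_start, 1.5e6)
  expect_equal(iv$outer_end, 3.6e6)
  expect_equal(iv$bracket_size_bp, 2.1e6)
  # single positive: inner width zero, bracket from the flanking negatives
  pat1 <- data.frame(chrom = "I", pos = c(1e6, 2e6, 3e6),
                     call = c(FALSE, TRUE, FALSE))
  iv1 <- inferInterval(pat1, 15e6)
  expect_equal(iv1$size_bp, 0)
  expect_equal(iv1$bracket_size_bp, 2e6)
  # all positive: the interval spans the whole chromosome
  pat2 <- data.frame(chrom = "I", pos = c(1e6, 7e6, 14e6), call = TRUE)
  iv2 <- inferInterval(pat2, 15e6)
  expect_equal(iv2$outer_start, 0)
  expect_equal(iv2$outer_end, 15e6)
  # no positive: a typed error
  pat3 <- transform(pat2, call = FALSE)
  expect_error(inferInterval(pat3, 15e6), class = "introMap_no_positive")
  expect_error(inferInterval(rbind(pat, transform(pat, chrom = "II")), 15e6),
               "one chromosome")
})

test_that("discontinuous segments split on single negative calls", {
  pos <- c(1e6, 2e6, 3e6, 4e6)
  seg2 <- detectSegments(data.frame(chrom = "I", pos = pos,
                                    call = c(TRUE, TRUE, FALSE, TRUE)), 15e6)
  expect_equal(nrow(seg2), 2)
  expect_equal(seg2$inner_end[1], 2e6)
  expect_equal(seg2$inner_start[2], 4e6)
  seg1 <- detectSegments(data.frame(chrom = "I", pos = pos,
                                    call = c(FALSE, TRUE, TRUE, FALSE)), 15e6)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$size_bp, 1e6)
  seg0 <- detectSegments(data.frame(chrom = "I", pos = pos, call = FALSE),
                         15e6)
  expect_equal(nrow(seg0), 0)
})

test_that("interval reports print positions and sizes in Mb", {
  iv <- inferInterval(data.frame(chrom = "I",
                                 pos = c(1.5e6, 2.1e6, 3.0e6, 3.6e6),
                                 call = c(FALSE, TRUE, TRUE, FALSE)), 15e6)
  rep <- intervalReport("demo-line", iv)
  expect_equal(rep$linkage_group, "Chrom I")
  expect_equal(rep$physical_position, "2.1 to 3.0 Mb")
  expect_equal(rep$introgression_size, "0.9 Mb")
})

test_that("denser panels never widen the negative bracket", {
  g <- defaultKaryotype(chromLength = 15e6, nAutosomes = 1)
  sparse <- coordinatePanel(g, primersPerChromosome = 10)
  # adding primers (here an interleaved second layout) to the sparse panel
  extra <- coordinatePanel(g, primersPerChromosome = 7)
  extra$id <- paste0(extra$id, "x")
  dense <- rbind(sparse, extra)
  set.seed(52)
  tested <- 0
  for (k in 1:40) {
    a <- runif(1, 0, 13e6); b <- a + runif(1, 0.5e6, 2e6)
    marker <- MarkerLocus("I", (a + b) / 2)
    ind <- syntheticCarrier(g, marker, a, b)
    mkpat <- function(panel) {
      rows <- panel[panel$chrom == "I", ]
      calls <- vapply(seq_len(nrow(rows)), function(i)
        insilicoPcrCoordinate(ind, rows[i, ]), logical(1))
      data.frame(chrom = "I", pos = (rows$left_start + rows$right_end) / 2,
                 call = calls)
    }
    ps <- mkpat(sparse); pd <- mkpat(dense)
    if (!any(ps$call) || !any(pd$call)) next
    ivs <- inferInterval(ps, 15e6); ivd <- inferInterval(pd, 15e6)
    expect_gte(ivd$outer_start, ivs$outer_start)
    expect_lte(ivd$outer_end, ivs$outer_end)
    # and the true marker stays inside both outer brackets
    expect_true(marker@position >= ivs$outer_start &&
                  marker@position <= ivs$outer_end)
    tested <- tested + 1
  }
  expect_gt(tested, 20)
})

test_that("the F2 marker fraction matches the gamete-table oracle", {
  expect_equal(expectedF2MutantGfpFraction(0.5), 0.75)
  expect_equal(expectedF2MutantGfpFraction(0), 0)
  expect_equal(expectedF2MutantGfpFraction(0.25), 0.4375)
  for (r in seq(0, 0.5, by = 0.05))
    expect_equal(expectedF2MutantGfpFraction(r), f2MutantMarkerOracle(r),
                 tolerance = 1e-12)
  expect_error(expectedF2MutantGfpFraction(0.6), "0, 0.5")
})

test_that("recombination estimation inverts the F2 expectation", {
  expect_equal(estimateRecombination(0, 100)$r_hat, 0)
  expect_equal(estimateRecombination(75, 25)$r_hat, 0.5)
  expect_error(estimateRecombination(0, 0), "positive")
  # exact recovery on noiseless proportions
  for (r in seq(0, 0.5, by = 0.05)) {
    p <- expectedF2MutantGfpFraction(r)
    est <- estimateRecombination(p * 1e6, (1 - p) * 1e6)
    expect_equal(est$r_hat, r, tolerance = 1e-9)
  }
  # simulated counts at r = 0.1, n = 5000: within 3 binomial SE
  set.seed(53)
  n <- 5000
  p <- expectedF2MutantGfpFraction(0.1)
  npos <- rbinom(1, n, p)
  est <- estimateRecombination(npos, n - npos)
  seR <- sqrt(p * (1 - p) / n) / (2 - 2 * 0.1)
  expect_lt(abs(est$r_hat - 0.1), 3 * seR)
})
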
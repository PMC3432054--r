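karyo6 <- function() defaultKaryotype(chromLength = 15e6, nAutosomes = 5)

test_that("the F1 is a heterozygous female carrying the marker", {
  g <- karyo6()
  marker <- MarkerLocus("II", 1.875e6)
  f1 <- makeF1(g, g, marker)
  expect_equal(f1@sex, "female")
  expect_equal(f1@generation, 1)
  expect_true(markerCarrier(f1))
  st <- segmentStats(f1)
  # exactly half the diploid genome is donor
  expect_equal(st$totalDonorBp, sum(chromLengths(g)))
  expect_equal(st$markerLinkedBp, 15e6)
  # X-linked marker from the donor father sits on one full donor X
  fx <- makeF1(g, g, MarkerLocus("X", 5e6))
  expect_true(markerCarrier(fx))
  xh <- fx@haplotypes[["X"]]
  expect_setequal(vapply(xh, function(h) h$origins[1], character(1)),
                  c("donor", "recipient"))
})

test_that("meiosis on identical haplotypes returns them unchanged", {
  map <- armWeightedMap(c(I = 15e6))
  h <- newHaplotype(15e6, "recipient")
  set.seed(41)
  for (model in c("obligate_single", "poisson")) {
    g <- meioseHaplotypes(h, h, map, "I", model)
    expect_identical(haplotypeSegments(g), haplotypeSegments(h))
  }
})

test_that("obligate-single meiosis transmits a recombinant exactly half the time", {
  map <- armWeightedMap(c(I = 15e6))
  hd <- newHaplotype(15e6, "donor")
  hr <- newHaplotype(15e6, "recipient")
  set.seed(42)
  n <- 2000
  rec <- vapply(seq_len(n), function(i) {
    g <- meioseHaplotypes(hd, hr, map, "I", "obligate_single")
    length(g$origins) > 1L
  }, logical(1))
  expect_lt(abs(mean(rec) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("poisson meiosis produces the map length in crossovers per gamete", {
  map <- uniformMap(c(I = 15e6), cM = 50)
  hd <- newHaplotype(15e6, "donor")
  hr <- newHaplotype(15e6, "recipient")
  set.seed(43)
  n <- 4000
  junctions <- vapply(seq_len(n), function(i) {
    g <- meioseHaplotypes(hd, hr, map, "I", "poisson")
    length(g$origins) - 1L
  }, numeric(1))
  # mean junction count = map length in Morgans = 0.5
  expect_lt(abs(mean(junctions) - 0.5), 3 * sd(junctions) / sqrt(n))
})

test_that("gametes tile the chromosome in canonical merged form", {
  set.seed(44)
  maps <- list(armWeightedMap(c(I = 15e6)), uniformMap(c(I = 15e6), cM = 120))
  for (k in 1:150) {
    map <- maps[[k %% 2 + 1]]
    model <- c("obligate_single", "poisson")[k %% 2 + 1]
    # random starting haplotypes built from random junctions
    mk <- function() {
      cuts <- sort(runif(sample(0:4, 1), 0, 15e6))
      .a <- newHaplotype(15e6, "donor"); .b <- newHaplotype(15e6, "recipient")
      introMap:::.recombineHaplotypes(.a, .b, cuts,
                                      startWith = sample(1:2, 1))
    }
    g <- meioseHaplotypes(mk(), mk(), map, "I", model)
    segs <- haplotypeSegments(g)
    expect_equal(segs$start[1], 0)
    expect_equal(segs$end[nrow(segs)], 15e6)
    if (nrow(segs) > 1) {
      expect_equal(segs$start[-1], segs$end[-nrow(segs)])
      expect_true(all(segs$origin[-1] != segs$origin[-nrow(segs)]))
    }
    expect_true(all(segs$end > segs$start))
  }
})

test_that("backcross offspring are marker-positive about half the time per trial", {
  g <- defaultKaryotype(chromLength = 2e6, nAutosomes = 1)
  map <- armWeightedMap(g)
  marker <- MarkerLocus("I", 5e5)
  n <- 300
  ok <- vapply(seq_len(n), function(i) {
    scheme <- crossScheme(generations = 1, broodSize = 1, seed = 1000 + i)
    f1 <- makeF1(g, g, marker, scheme)
    !is.null(tryCatch(backcrossOnce(f1, scheme, map),
                      introMap_brood_exhausted = function(e) NULL))
  }, logical(1))
  expect_lt(abs(mean(ok) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("X-linked selection respects the large-X rule and alternation", {
  g <- defaultKaryotype(chromLength = 2e6, nAutosomes = 1)
  map <- armWeightedMap(g)
  marker <- MarkerLocus("X", 5e5)
  # large-X effect: every selected carrier is female
  scheme <- crossScheme("x_linked", largeXEffect = TRUE, generations = 5,
                        seed = 77)
  sim <- runIntrogression(g, g, marker, scheme, map)
  expect_true(all(vapply(sim$trajectory, function(i) i@sex, character(1)) ==
                    "female"))
  # without it, carrier sex alternates with generation parity
  scheme2 <- crossScheme("x_linked", largeXEffect = FALSE, generations = 4,
                         seed = 78)
  sim2 <- runIntrogression(g, g, marker, scheme2, map)
  sexes <- vapply(sim2$trajectory, function(i) i@sex, character(1))
  expect_equal(sexes, c("female", "male", "female", "male", "female"))
  # male X carriers are hemizygous and pass the X intact to daughters
  male <- sim2$trajectory[[2]]
  expect_length(male@haplotypes[["X"]], 1L)
  daughter <- sim2$trajectory[[3]]
  expect_true(any(vapply(daughter@haplotypes[["X"]], function(h)
    identical(h, male@haplotypes[["X"]][[1]]), logical(1))))
})

test_that("a markerless cross exhausts the brood", {
  g <- defaultKaryotype(chromLength = 2e6, nAutosomes = 1)
  map <- armWeightedMap(g)
  scheme <- crossScheme(generations = 1, seed = 5)
  f1 <- makeF1(g, g, MarkerLocus("I", 5e5), scheme)
  # recipient x recipient control: no donor segment carries the marker
  pure <- syntheticCarrier(g, MarkerLocus("I", 5e5), 4e5, 6e5)
  pure@haplotypes[["I"]][[1]] <- newHaplotype(2e6, "recipient")
  expect_error(backcrossOnce(pure, scheme, map),
               class = "introMap_brood_exhausted")
})

test_that("introgression trajectories are selected, deterministic and seed-sensitive", {
  g <- defaultKaryotype(chromLength = 15e6, nAutosomes = 2)
  map <- armWeightedMap(g)
  marker <- MarkerLocus("I", 1.875e6)
  scheme <- crossScheme(generations = 4, seed = 9)
  sim <- runIntrogression(g, g, marker, scheme, map)
  expect_length(sim$trajectory, 5)  # F1 + one per backcross generation
  expect_true(all(vapply(sim$trajectory, markerCarrier, logical(1))))
  expect_equal(sim$stats$generation, 1:5)
  sim2 <- runIntrogression(g, g, marker, scheme, map)
  expect_identical(sim$stats, sim2$stats)
  final1 <- sim$trajectory[[5]]@haplotypes
  final2 <- sim2$trajectory[[5]]@haplotypes
  expect_identical(final1, final2)
  sim3 <- runIntrogression(g, g, marker,
                           crossScheme(generations = 4, seed = 10), map)
  expect_false(identical(sim$stats, sim3$stats))
})

test_that("unlinked donor genome decays by half per generation and vanishes by t=10", {
  g <- Genome("donor", lengths = c(I = 15e6, II = 15e6))
  map <- armWeightedMap(g)
  marker <- MarkerLocus("I", 1.875e6)
  nrep <- 300
  fracs <- matrix(NA_real_, nrep, 3)
  for (r in seq_len(nrep)) {
    sim <- runIntrogression(g, g, marker,
                            crossScheme(generations = 3, seed = 2000 + r),
                            map)
    for (t in 1:3) {
      ind <- sim$trajectory[[t + 1]]
      unl <- sum(vapply(ind@haplotypes[["II"]], introMap:::.donorBp,
                        numeric(1)))
      fracs[r, t] <- unl / (2 * 15e6)
    }
  }
  for (t in 1:3) {
    expected <- (1 / 2)^(t + 1)
    se <- sd(fracs[, t]) / sqrt(nrep)
    expect_lt(abs(mean(fracs[, t]) - expected), 3 * se + 0.01)
  }
  # after 10 generations the unlinked content is essentially gone
  left <- vapply(1:30, function(r) {
    sim <- runIntrogression(g, g, marker,
                            crossScheme(generations = 10, seed = 4000 + r),
                            map)
    ind <- sim$trajectory[[11]]
    sum(vapply(ind@haplotypes[["II"]], introMap:::.donorBp, numeric(1))) /
      (2 * 15e6)
  }, numeric(1))
  expect_lt(mean(left), 0.02)
})

test_that("segment statistics report the marker-linked fragment", {
  g <- karyo6()
  f1 <- makeF1(g, g, MarkerLocus("I", 2.5e6))
  expect_equal(segmentStats(f1)$markerLinkedBp, 15e6)
  # hand-built carrier: donor segment [2.1, 3.0) Mb containing the marker
  ind <- syntheticCarrier(g, MarkerLocus("I", 2.5e6), 2.1e6, 3.0e6)
  st <- segmentStats(ind)
  expect_equal(st$markerLinkedBp, 0.9e6)
  expect_equal(st$totalDonorBp, 0.9e6)
  expect_equal(unname(st$donorSegments["I"]), 1L)
  # invariant under canonical re-merge of split segments
  ind2 <- ind
  ind2@haplotypes[["I"]][[1]] <- haplotypeFromSegments(
    c(0, 2.1e6, 2.5e6, 3.0e6), c(2.1e6, 2.5e6, 3.0e6, 15e6),
    c("recipient", "donor", "donor", "recipient"))
  expect_equal(segmentStats(ind2), st)
  # marker-negative individuals report an absent linked length
  neg <- syntheticCarrier(g, MarkerLocus("I", 2.5e6), 2.1e6, 3.0e6)
  neg@haplotypes[["I"]][[1]] <- newHaplotype(15e6, "recipient")
  expect_true(is.na(segmentStats(neg)$markerLinkedBp))
})

test_that("the closed-form flank expectation behaves at its limits", {
  expect_equal(expectedFlankLength(5, 0), 0)
  expect_equal(expectedFlankLength(1, 50), 1, tolerance = 1e-9)
  expect_equal(expectedFlankLength(8, 0.25), 0.1080831, tolerance = 1e-6)
  # decreasing in t for fixed flank
  v <- expectedFlankLength(1:15, 0.25)
  expect_true(all(diff(v) < 0))
  expect_error(expectedFlankLength(0, 0.1), "t >= 1")
})

test_that("marker-linked donor length shrinks in expectation across generations", {
  g <- defaultKaryotype(chromLength = 15e6, nAutosomes = 1)
  map <- armWeightedMap(g)
  marker <- MarkerLocus("I", 1.875e6)
  nrep <- 120
  lens <- matrix(NA_real_, nrep, 9)
  for (r in seq_len(nrep)) {
    sim <- runIntrogression(g, g, marker,
                            crossScheme(generations = 8, seed = 6000 + r),
                            map)
    lens[r, ] <- sim$stats$marker_linked_bp
  }
  m <- colMeans(lens)
  expect_true(all(diff(m) <= 0))
})
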
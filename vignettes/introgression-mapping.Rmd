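---
title: "Species-specific PCR panels and marker-selected introgression: models and design choices"
author: "introMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-specific PCR panels and marker-selected introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(introMap)
```

This vignette is the package's account of the science it implements: the
models, the tunable parameters and their defaults, what the synthetic data
emulate (and what they do not), and the numerical and design choices made
where the method leaves room.

## 1. The mapping idea

A dominant visible marker integrated into a donor genome is pushed into a
sister-species background by repeated backcrossing, selecting a
marker-positive animal each generation. Recombination whittles the donor
genome down to the fragment physically linked to the marker. A panel of
primer pairs that amplify donor but never recipient sequence converts a
single animal into an ordered presence/absence vector along each
chromosome; the outermost positive primers span the retained fragment and
the nearest flanking negative primers bound the insertion site. One
genotyping therefore yields the linkage group, an interval for the
insertion, and the introgression size, without making the locus homozygous
— heterozygous templates amplify just as well, which is what makes the
readout dominant-marker-friendly.

## 2. Genomes, maps, coordinates

* `Genome` holds named chromosomes with optional sequence; most of the
  simulator runs in coordinate-only mode. The default karyotype is five
  autosomes plus an X, 15 Mb each — the scale of the modelled species pair.
* The `GeneticMap` is piecewise linear between anchor points. No map
  function (Haldane/Kosambi) is applied because crossovers are *simulated*
  in genetic coordinates; map functions only matter when converting
  recombination fractions to distances, which we never do. The default
  `armWeightedMap()` gives each chromosome 50 cM with 20 cM on each
  physical arm quarter and 10 cM across the central half, reproducing the
  arm-biased recombination of Caenorhabditis chromosomes; it is why
  physical resolution is high on arms and poor in centres.
* Annotation lives in a `GRanges` (1-based, the Bioconductor convention),
  converted at the I/O boundary from GFF3 (1-based closed) and BED
  (0-based half-open); `featureTable()` exposes the 0-based half-open view.
  All other coordinates in the package — primer binding sites, ancestry
  segments, marker positions — are 0-based half-open doubles. User-facing
  reports print positions in Mb with one decimal.
* The marker cassette is recorded as a zero-footprint locus: its length is
  kept as an annotation but the sequence is not physically inserted, so
  donor coordinates remain valid for the panel and the simulator. Nothing
  downstream depends on the cassette sequence, only on carrier status.

## 3. The synthetic sister pair

`generateSisterPair()` derives the recipient from the donor directly — no
common ancestor is simulated, because every downstream method consumes only
the *contrast* between the genomes:

| parameter | default | rationale |
|---|---|---|
| exon fraction | 0.25 | gene-dense nematode genome |
| repeat fraction | 0.10 | tandem tracts in intergenic sequence, shared and conserved between the genomes, so the repeat-exclusion rule has something to exclude |
| exonic substitutions | 0.02 /base | coding conservation; exons still cross-align between the species |
| non-exonic substitutions | 0.45 /base | see below |
| non-exonic indel initiation | 0.02 /base, geometric lengths (mean 6) | confined to non-exonic, non-repeat sequence so the exon annotation stays valid on both genomes |
| contaminant contigs | 0 | optional recipient-only contigs of unrelated sequence carrying donor-like exons, emulating cross-species contamination of a draft assembly |
| shared haplotype fraction | 0 | optional verbatim donor tracts in the recipient, emulating wild introgression between the species (a wild-isolate scenario); ground-truth tract coordinates are returned |

The non-exonic rate deserves its own paragraph. Under the +2/−3 scoring
scheme the expected per-aligned-base score drift is 5q − 3 for identity q,
so a 600 bp orthologous region stays above the score-50 specificity cutoff
whenever q ≳ 0.6: at 15% divergence every candidate region scores in the
hundreds against a *complete* recipient assembly and panel design is
impossible by construction. The real screen operated against a fragmentary
early assembly in which most non-coding regions simply had no counterpart.
With a complete synthetic recipient the same operating point — most regions
specific, roughly one in ten iterations rejected — requires the non-coding
sequence to be essentially unalignable, hence the 45% default (q = 0.55,
drift −0.25/base). Empirically this leaves ~90% of candidate regions at or
under the cutoff. Non-coding sequence between genuinely hybridizing sister
nematode species is indeed mostly unalignable; what the generator does
*not* emulate is assembly incompleteness, segmental duplication, or any
population-level variation, so passing tests say nothing about those
failure modes on real data.

## 4. Panel design

For each chromosome, targets are laid out over physical thirds with
density weights 0.4/0.2/0.4 (denser on arms, matching both the
recombination landscape and the lower marginal value of centre primers),
then each target walks outward in 1 kb steps, alternating right/left, up to
50 steps, until a 600 bp window passes all four gates:

1. wholly intron/intergenic, overlapping no repeat;
2. best local alignment against the recipient ≤ 50 (raw score; exactly 50
   is tolerated — "more than 50" is the rejection rule);
3. a primer pair exists under the physical constraints;
4. both primers pass the 3′-end filter.

**Alignment engine.** Scores are raw Smith-Waterman with match +2,
mismatch −3, gap open 5, gap extend 2 (gap of length L costs 5 + 2L), both
strands, clamped at zero — the classic default-parameter BLASTN scheme, so
the score-50 cutoff means what it meant there (≥ ~25 identical bases of
gapless identity trips it). Small problems run the exact DP
(`Biostrings::pairwiseAlignment`); genome-scale subjects use an 11-mer
seed-and-extend accelerator: exact 11-mer hits of the query seed padded
windows in which the exact DP is run, batched into a single alignment call
per strand. Alignments containing no exact 11-mer are below the screen's
detectability and score 0, mirroring the word-size-11 behaviour of the
original search. Correctness of the exact path is pinned to an independent
quadratic DP oracle in the test suite.

**3′-end filter.** A primer whose 3′ terminus matches the recipient
exactly over more than 8 bases is discarded (8 passes, 9 fails). The
exported `longestThreePrimeMatch()` searches exhaustively by binary search
over suffix lengths — occurrence is monotone in suffix length — but the
*design loop* restricts the search to windows of local similarity (11-mer
seed hits of the primer), for a statistical reason: a specific 9-mer occurs
by chance in a genome of size G with probability ≈ 1 − exp(−2G/4⁹), which
is ~1 for any G above a megabase. A genome-wide exact reading of the rule
would therefore reject every primer on any realistic genome; the rule is
only meaningful applied to an alignment report, which is how the design
loop applies it. The recorded `max_three_prime_match` audit field uses the
same hit-restricted search.

**Primer constraints** (where the protocol is silent, values are standard
practice): length 18–27 nt; melting temperature 55–62 °C by unified
nearest-neighbor thermodynamics at 0.25 µM primer and 0.2 M effective
monovalent cation (a Mg-corrected PCR buffer; the NN tables are
strand-symmetric, so a primer and its reverse complement share a Tm); GC
35–65%; no homopolymer run of five; product 150–800 bp. Among all valid
facing pairs the designer picks the smallest left/right Tm difference, ties
broken by leftmost coordinate then smallest right end — fully
deterministic, and independent of chromosome processing order.

**Audit.** `validatePanel()` re-amplifies every pair in sequence mode
against both genomes; pairs yielding a recipient product are `discarded`,
and retained = candidates − cross-amplifying. This is the in-silico
analogue of testing every pair on genomic DNA of both species, and it is
deliberately independent of the design-time screens.

## 5. The introgression simulator

Haplotypes are ordered donor/recipient ancestry segments (junction
representation) in canonical merged form; meiosis, statistics and
genotyping all operate on segments, never on sequence, which keeps a
15-generation, six-chromosome simulation in the tens of milliseconds.

* **Crossover models.** The default `obligate_single` places exactly one
  crossover per bivalent, uniform in genetic coordinates; the transmitted
  chromatid is recombinant with probability 1/2 and otherwise a parental
  haplotype — the near-complete crossover interference of Caenorhabditis.
  The `poisson` alternative draws Poisson(map length in Morgans) crossovers
  i.i.d. uniform in genetic coordinates on the transmitted chromatid. The
  protocol being modelled specifies neither; obligate-single is the
  biologically defensible default, and the Poisson model is kept because it
  admits a closed-form check: with marker-side selection the retained donor
  length on a flank of genetic extent d Morgans after t meioses is
  distributed min(d, Exp(t)), with expectation (1 − e^{−t·d})/t
  (`expectedFlankLength()`); the simulator reproduces it to Monte-Carlo
  error, and under these study conditions (arm marker at 10 cM, 50 cM
  arm-weighted chromosome, 8 generations) the mean marker-linked fragment
  comes out near 4.7–4.9 Mb — at the upper edge of the mapped-fragment
  scale, driven by the physically long, recombination-poor centre.
* **Sexes and the X.** The recipient species is gonochoristic; sex follows
  X0 determination (daughters receive the father's X, sons only the
  maternal X). F1 hybrid males are removed outright — modelled as absent
  rather than given a fertility parameter, matching the protocol. Autosomal
  schemes accept a marker-positive offspring of either sex; X-linked
  schemes with a large-X effect select females only; without it, carrier
  sex alternates with generation parity — which is also what the underlying
  genetics enforces, since a carrier male transmits his X intact to all
  daughters and to no sons.
* **Counting.** Generation t counts marker-selected meioses in the carrier
  lineage, F1 = 1; `runIntrogression(generations = g)` performs g
  backcrosses after the F1, so "8 backcross generations" examines the
  individual at t = 9 whose lineage has experienced 8 recombining,
  marker-selected meioses.
* **Brood logistics.** The protocol's specific animal counts are abstracted
  into a brood size (default 20) with a retry budget; they affect only the
  probability that a cross succeeds, not the genetics of the transmitted
  segments.
* **Randomness.** A single scheme seed owns the run. Every draw seeds a
  generator from (seed, generation, trial, chromosome-name hash), so
  per-chromosome streams are independent of chromosome ordering and runs
  are reproducible bit for bit.

## 6. Genotyping and inference

* **Coordinate mode** calls a pair positive iff one haplotype carries a
  single donor segment covering both primer intervals: trans
  configurations and segments ending between the primers cannot provide a
  contiguous template. **Sequence mode** demands an exact 15 nt 3′ core and
  at most 2 mismatches elsewhere, product ≤ 2 kb, either pair orientation.
  The binding rule is a deliberate simplification of hybridization
  kinetics and is the single place the two modes could diverge, so it is
  centralized and configurable; on rendered individuals (indel-free
  divergence, where the genomes share coordinates) the modes agree on every
  retained pair, and the suite asserts exactly that.
* **Hierarchical strategy.** Stage 1 runs one left/middle/right pair per
  autosome (15 reactions); the unique positive chromosome then gets its
  remaining pairs, totalling 15 + (n − 3) reactions (27 for a 15-pair
  chromosome); zero stage-1 positives trigger an X fallback; a known
  X-linked marker runs only the X panel. Positives on two or more
  chromosomes are reported as a flag rather than an error — with real
  assemblies such anomalies are worth surfacing, not hiding.
* **Intervals.** The reported introgression size is the span of the
  outermost positive primers (`size_bp`); the width between the flanking
  negative primers (`bracket_size_bp`, falling back to chromosome ends) is
  reported alongside. On published-style mapping tables the printed size
  equals the difference of the printed inner bounds, which is the
  convention adopted; one historical row whose printed size disagrees with
  its own bounds by 1 Mb is treated as irreproducible from the available
  description and excluded from exact checks. Runs of consecutive positives
  separated by a single negative are split into discontinuous segments.
* **Two-point linkage.** For a repulsion-phase F1 (dominant marker and
  recessive visible mutation on opposite homologs), the marker-positive
  fraction among mutant F2 is 2r − r²; `estimateRecombination()` inverts it
  as r̂ = 1 − √(n₋/n), clipped to [0, 0.5]. The expectation is verified
  against brute-force enumeration of the 4×4 gamete table, and the
  estimator recovers r exactly on noiseless proportions.

## 7. Numerical choices and degenerate inputs

Boundary readings: specificity keeps score = 50, the 3′ filter keeps
8 bases, both "more than" rules. Interval inference requires at least one
positive call and signals a typed error otherwise; brood exhaustion,
region exhaustion and panel infeasibility are likewise typed conditions
(`introMap_*`) so callers can retry or degrade gracefully. A chromosome
yielding fewer than three pairs aborts panel design: below that the
hierarchical strategy cannot even run its first stage. Zero-divergence
pairs make every region fail the specificity screen, and identical genomes
make `validatePanel()` discard everything — both are exercised in tests as
the degenerate limits of the design problem.

## 8. Problem sizes used in the checks

The test fixtures run the full pipeline at reduced scale — sister pairs of
two or three chromosomes at 120–150 kb with five pairs per chromosome,
chosen so a complete design-validate-simulate-genotype cycle stays in the
tens of seconds while exercising every code path; simulator moment checks
use 10,000 replicates per condition, interval-bracketing checks 1,000
simulated lines, and the oracle-equivalence batteries 1,000 random cases.
The headline simulation (mean marker-linked fragment, 8 generations on the
15 Mb arm-weighted karyotype) uses 500 replicates, which puts the
Monte-Carlo standard error near 0.17 Mb.

## 9. Known limitations

* The divergence model is i.i.d. per base within a class: no rate
  variation along chromosomes, no codon structure, no transposable
  elements; repeat tracts are simple tandem motifs.
* The seeded alignment path shares the blind spot of any word-11 search:
  orthologous regions so diverged that no exact 11-mer survives score 0
  even when the exact DP would score above the cutoff. The sequence-mode
  PCR audit is the backstop, exactly as wet-lab validation was.
* Primer thermodynamics stop at Tm/GC/homopolymer rules — no dimer or
  hairpin simulation, no multiplexing.
* The simulator models no fitness variation beyond F1 male removal and
  marker selection; hybrid-incompatibility loci, segregation distortion
  and viability selection are out of scope, though they are precisely what
  the produced introgression lines would be used to find.
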
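Package: introMap
Title: Species-Specific PCR Panels and Backcross Introgression Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simultaneous mapping of dominant loci and introgression-fragment
    sizes between a sister-species pair. Designs evenly spaced, arm-biased
    panels of species-specific PCR primer pairs that amplify a donor genome
    but not its sister recipient genome (local-alignment specificity screen
    and 3'-end exact-match filter), simulates marker-selected backcross
    introgression with junction/segment ancestry under obligate-single or
    Poisson crossover models, performs in-silico single-worm PCR genotyping
    (coordinate and sequence modes) with a two-stage hierarchical strategy,
    and infers the physical interval and size of the retained donor fragment
    from presence/absence patterns, including discontinuous segments and a
    two-point F2 linkage estimator. A synthetic sister-genome generator with
    conserved exons, diverged non-coding sequence, shared repeat tracts,
    contaminant contigs and shared wild haplotypes makes the whole pipeline
    exercisable without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
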
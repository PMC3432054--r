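# Shared fixtures, generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Two autosomes + X, 150 kb each, default divergence.
testPair <- function() {
  .cached("pair", generateSisterPair(
    divergenceConfig(seed = 42, nAutosomes = 2, chromLengthBp = 150e3)))
}

testMap <- function() {
  .cached("map", armWeightedMap(testPair()$donor))
}

testSpec <- function() {
  panelSpec(primersPerChromosome = 5, productSizeRange = c(150, 500))
}

# Designed + audited panel on the test pair (the expensive fixture).
testPanel <- function() {
  .cached("panel", {
    pair <- testPair()
    design <- designPanel(pair$donor, pair$recipient, pair$annotation,
                          testMap(), testSpec())
    audit <- validatePanel(design$panel, pair$donor, pair$recipient)
    list(design = design, audit = audit, panel = audit$panel)
  })
}

# Indel-free pair (shared coordinates) for sequence-rendering checks.
noIndelPair <- function() {
  .cached("noIndelPair", generateSisterPair(
    divergenceConfig(seed = 7, nAutosomes = 1, chromLengthBp = 120e3,
                     indelRateNonexonic = 0)))
}

noIndelPanel <- function() {
  .cached("noIndelPanel", {
    pair <- noIndelPair()
    design <- designPanel(pair$donor, pair$recipient, pair$annotation,
                          armWeightedMap(pair$donor), testSpec())
    validatePanel(design$panel, pair$donor, pair$recipient)$panel
  })
}
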
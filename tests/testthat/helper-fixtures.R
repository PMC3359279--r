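# shared fixture builders for the test suite; everything is generated in
# code, nothing is read from disk except explicit round-trip tests

# small expression matrix with given dims and dimnames
makeExpr <- function(nf = 6, ns = 4, species = "species1", seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nf * ns), nf, ns,
              dimnames = list(sprintf("g%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  ExpressionMatrix(m, species = species)
}

# hand-built CoModule over explicit universes; scores: named numeric over
# members, expanded to the full universe with zeros
makeCoModule <- function(universe1, universe2, universeS,
                         members1, members2, membersS,
                         t1 = 3, t2 = 3, ts = 2) {
  expand <- function(universe, members) {
    s <- setNames(numeric(length(universe)), universe)
    if (is.null(names(members)))
      members <- setNames(rep(1, length(members)), members)
    s[names(members)] <- members / max(members)
    s
  }
  new("CoModule",
      sharedScores = expand(universeS, membersS),
      featureScores1 = expand(universe1, members1),
      featureScores2 = expand(universe2, members2),
      thresholds = c(feature1 = t1, feature2 = t2, shared = ts),
      iterations = 1L, converged = TRUE, nSeeds = 1L)
}

# a small planted simulation plus its HOG-merged matrices
makePlantedRun <- function(seed, nSeeds = 200, config = simConfig(seed = seed),
                           gridSeed = seed) {
  sim <- simulatePair(config)
  E1 <- mergeIntoHOGs(sim$E1, sim$hogs)
  E2 <- mergeIntoHOGs(sim$E2, sim$hogs)
  raw <- NULL
  if (nSeeds > 0) {
    set.seed(gridSeed)
    raw <- runPPAGrid(E1, E2, makeRandomSeeds(sampleIds(E1), nSeeds))
  }
  list(sim = sim, E1 = E1, E2 = E2, raw = raw)
}

# population-sd z-score, written independently of the package
popZ <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
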
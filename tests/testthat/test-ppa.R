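test_that("normalization centers and scales with the population convention", {
  m <- matrix(c(1, 2, 3, 4, 2, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  n <- suppressWarnings(normalizeForProjection(m))  # column s2 is constant
  expect_equal(unname(n$row["a", ]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)

  # random matrix: every row/column has mean 0 and population sd 1
  set.seed(4)
  m <- matrix(rnorm(120), 20, 6,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:6)))
  n <- normalizeForProjection(m)
  expect_equal(unname(rowMeans(n$row)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(n$row^2))), rep(1, 20), tolerance = 1e-12)
  expect_equal(unname(colMeans(n$column)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(n$column^2))), rep(1, 6),
               tolerance = 1e-12)

  # constant rows become zero with a warning
  m[3, ] <- 5
  expect_warning(n <- normalizeForProjection(m), "constant")
  expect_equal(unname(n$row[3, ]), rep(0, 6))
})

test_that("thresholding keeps the upper tail and rescales to (0, 1]", {
  # constant vector: population sd 0, nothing strictly exceeds the mean
  expect_equal(sum(thresholdScores(c(1, 1, 1, 1), 1) > 0), 0)

  # hand case: mean 2.5, population sd ~4.330, cutoff ~6.83
  s <- thresholdScores(c(0, 0, 0, 10), 1)
  expect_equal(unname(s), c(0, 0, 0, 1))
  expect_gt(10, 2.5 + 1 * sqrt(mean((c(0, 0, 0, 10) - 2.5)^2)))

  # large t empties any vector
  set.seed(5)
  x <- rnorm(100)
  expect_equal(sum(thresholdScores(x, 50) > 0), 0)

  # survivors match a directly computed support and max-rescaling
  for (i in 1:20) {
    x <- rnorm(40)
    t <- runif(1, 0, 3)
    cut <- mean(x) + t * sqrt(mean((x - mean(x))^2))
    keep <- x > cut & x > 0
    s <- thresholdScores(x, t)
    expect_identical(which(s > 0), which(keep))
    if (any(keep)) expect_equal(s[keep], x[keep] / max(x[keep]))
  }
})

test_that("threshold support is anti-monotone in t", {
  set.seed(6)
  for (i in 1:50) {
    x <- rnorm(sample(5:60, 1)) * runif(1, 0.1, 10)
    grid <- sort(runif(6, 0, 4))
    supports <- lapply(grid, function(t) which(thresholdScores(x, t) > 0))
    for (j in seq_len(5))
      expect_true(all(supports[[j + 1]] %in% supports[[j]]))
  }
})

test_that("random seeds are uniform subsets with uniform sizes", {
  expect_error(makeRandomSeeds(character(0), 5))
  expect_error(makeRandomSeeds("H1", 0))
  set.seed(1)
  expect_true(all(vapply(makeRandomSeeds("H1", 5), identical, TRUE, "H1")))

  set.seed(2)
  ids <- sprintf("H%02d", 1:27)
  sizes <- lengths(makeRandomSeeds(ids, 10000))
  chi <- chisq.test(tabulate(sizes, nbins = 27))
  expect_gt(chi$p.value, 0.01)
})

test_that("the iteration returns NULL on degenerate input and errors on misaligned matrices", {
  z <- matrix(0, 5, 4, dimnames = list(sprintf("g%d", 1:5),
                                       sprintf("s%d", 1:4)))
  E1 <- ExpressionMatrix(z, "a")
  E2 <- ExpressionMatrix(z, "b")
  expect_null(suppressWarnings(ppaIterate(E1, E2, "s1", c(2, 2, 1))))

  m2 <- z; colnames(m2) <- sprintf("x%d", 1:4)
  expect_error(ppaIterate(E1, ExpressionMatrix(m2, "b"), "s1", c(2, 2, 1)),
               "share")
})

test_that("the iteration recovers a planted module from its organ seed", {
  run <- makePlantedRun(31, nSeeds = 0)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (k in 1:3) {
    m <- run$sim$truth$modules[[k]]
    cm <- ppaIterate(run$E1, run$E2, m$hogs, c(2.5, 2.5, 1))
    expect_s4_class(cm, "CoModule")
    expect_true(cm@converged)
    # the organ set is recovered exactly; near-cutoff probes may drop, so
    # the feature memberships are held to a high Jaccard
    expect_setequal(sharedMembers(cm), m$hogs)
    expect_gte(jac(featureMembers(cm, 1), m$probes1), 0.9)
    expect_gte(jac(featureMembers(cm, 2), m$probes2), 0.9)
  }

  # determinism: bitwise-equal scores on a second run
  m <- run$sim$truth$modules[[1]]
  cm <- ppaIterate(run$E1, run$E2, m$hogs, c(2.5, 2.5, 1))
  cm2 <- ppaIterate(run$E1, run$E2, m$hogs, c(2.5, 2.5, 1))
  expect_identical(sharedScores(cm), sharedScores(cm2))
  expect_identical(featureScores(cm, 1), featureScores(cm2, 1))
})

test_that("a converged co-module is a fixed point of the pure-R cycle", {
  run <- makePlantedRun(32, nSeeds = 0)
  for (k in 1:3) {
    m <- run$sim$truth$modules[[k]]
    cm <- ppaIterate(run$E1, run$E2, m$hogs, c(3, 3, 1.5))
    if (is.null(cm)) next
    cyc <- ppaCycle(run$E1, run$E2, cm)
    expect_identical(names(which(cyc$f1 > 0)), featureMembers(cm, 1))
    expect_identical(names(which(cyc$f2 > 0)), featureMembers(cm, 2))
    expect_identical(names(which(cyc$shared > 0)), sharedMembers(cm))
  }
})

test_that("the grid run dedupes fixed points and is reproducible", {
  expect_length(runPPAGrid(makeExpr(6, 4), makeExpr(6, 4, "b", seed = 2),
                           list()), 0)

  # one planted module: after the size filter a single distinct co-module
  # remains, and it matches the planted truth
  cfg <- simConfig(nPlanted = 1, organsPerModule = c(2L, 2L), seed = 33)
  sim <- simulatePair(cfg)
  E1 <- mergeIntoHOGs(sim$E1, sim$hogs)
  E2 <- mergeIntoHOGs(sim$E2, sim$hogs)
  set.seed(10)
  seeds <- makeRandomSeeds(sampleIds(E1), 100)
  raw <- runPPAGrid(E1, E2, seeds, featureGrid = 2.5, sharedGrid = 1.5)
  big <- filterMinProbes(raw)
  expect_length(big, 1)
  m <- sim$truth$modules[[1]]
  expect_setequal(sharedMembers(big[[1]]), m$hogs)
  expect_gt(length(intersect(featureMembers(big[[1]], 1), m$probes1)) /
              length(union(featureMembers(big[[1]], 1), m$probes1)), 0.9)

  # full-run determinism given the seed used for makeRandomSeeds
  set.seed(10)
  raw2 <- runPPAGrid(E1, E2, makeRandomSeeds(sampleIds(E1), 100),
                     featureGrid = 2.5, sharedGrid = 1.5)
  expect_equal(length(raw), length(raw2))
  expect_identical(sharedScores(raw[[1]]), sharedScores(raw2[[1]]))
})

test_that("two disjoint planted modules are both recovered by the default grid", {
  cfg <- simConfig(nPlanted = 2, seed = 34)
  sim <- simulatePair(cfg)
  E1 <- mergeIntoHOGs(sim$E1, sim$hogs)
  E2 <- mergeIntoHOGs(sim$E2, sim$hogs)
  set.seed(11)
  raw <- runPPAGrid(E1, E2, makeRandomSeeds(sampleIds(E1), 500))
  expect_gte(length(raw), 2)
  rec <- recoveryScore(sim$truth, raw)
  expect_true(all(rec$organ_jaccard >= 0.9))
  expect_true(all(rec$gene1_jaccard >= 0.9))
  expect_true(all(rec$gene2_jaccard >= 0.9))
})

test_that("the same engine runs the gene-shared configuration and pairs homologous organs", {
  # single-organ planted modules; ortholog pairs form the shared dimension
  sim <- simulatePair(simConfig(organsPerModule = c(1L, 1L), seed = 21))
  cfg <- runConfig("gene-shared", expr1 = sim$E1, expr2 = sim$E2,
                   hogs = sim$hogs, orth = sim$orth, probes = sim$probes,
                   nSeeds = 300, seed = 3)
  res <- runPipeline(cfg)
  expect_gt(length(res$comodules), 0)
  hogOf <- function(x) sub("^species[12]:", "", x)
  paired <- vapply(res$comodules, function(cm) {
    f1 <- hogOf(featureMembers(cm, 1))
    f2 <- hogOf(featureMembers(cm, 2))
    length(f1) > 0 && setequal(f1, f2)
  }, TRUE)
  # every reported co-module couples each organ with its homolog
  expect_true(all(paired))
  truthHogs <- vapply(sim$truth$modules, function(m) m$hogs, "")
  foundHogs <- unique(unlist(lapply(res$comodules, function(cm)
    hogOf(featureMembers(cm, 1)))))
  expect_gt(length(intersect(truthHogs, foundHogs)), 0)
})
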
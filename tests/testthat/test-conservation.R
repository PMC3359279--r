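test_that("families are the connected components of the bipartite pair graph", {
  # single one-to-one pair
  fam <- buildFamilies(OrthologyMap("h1", "m1"))
  expect_length(geneFamilies(fam), 1)
  expect_identical(geneFamilies(fam)[[1]]$species1, "h1")
  expect_identical(geneFamilies(fam)[[1]]$species2, "m1")

  # shared genes merge pairs into one family
  fam <- buildFamilies(OrthologyMap(c("h1", "h1", "h2"),
                                    c("m1", "m2", "m2")))
  expect_length(geneFamilies(fam), 1)
  expect_setequal(geneFamilies(fam)[[1]]$species1, c("h1", "h2"))
  expect_setequal(geneFamilies(fam)[[1]]$species2, c("m1", "m2"))

  # random orthologies match an independently coded union-find
  set.seed(12)
  for (rep in 1:10) {
    g1 <- sprintf("h%d", sample(30, 40, replace = TRUE))
    g2 <- sprintf("m%d", sample(30, 40, replace = TRUE))
    pairs <- unique(data.frame(g1, g2))
    fam <- buildFamilies(OrthologyMap(pairs$g1, pairs$g2))
    # union-find oracle
    ids <- unique(c(paste0("A", pairs$g1), paste0("B", pairs$g2)))
    parent <- setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (i in seq_len(nrow(pairs))) {
      a <- find(paste0("A", pairs$g1[i])); b <- find(paste0("B", pairs$g2[i]))
      if (a != b) parent[[a]] <- b
    }
    roots <- vapply(ids, find, "")
    expect_identical(length(geneFamilies(fam)), length(unique(roots)))
    # each package family is contained in one oracle component
    for (f in geneFamilies(fam)) {
      r <- unique(roots[c(paste0("A", f$species1), paste0("B", f$species2))])
      expect_length(r, 1)
    }
  }
})

test_that("gamma reproduces the worked toy example and its bounds", {
  # 5 one-to-one families; co-module holds 4 species-1 and 3 species-2
  # genes, 2 families span both sides: n_og = 2, nfam_h = 4, nfam_m = 3
  orth <- OrthologyMap(paste0("h", 1:5), paste0("m", 1:5))
  fam <- buildFamilies(orth)
  g <- gammaConservation(c("h1", "h2", "h3", "h4"), c("m1", "m2", "m5"), fam,
                         paste0("h", 1:5), paste0("m", 1:5))
  expect_identical(g$n_og, 2L)
  expect_identical(g$nfam_h, 4L)
  expect_identical(g$nfam_m, 3L)
  expect_equal(g$gamma, 2 / 3)

  # fully conserved one-to-one co-module: gamma = 1
  g1 <- gammaConservation(paste0("h", 1:5), paste0("m", 1:5), fam,
                          paste0("h", 1:5), paste0("m", 1:5))
  expect_equal(g1$gamma, 1)

  # no family on both sides: gamma = 0
  g0 <- gammaConservation(c("h1", "h2"), c("m3", "m4"), fam,
                          paste0("h", 1:5), paste0("m", 1:5))
  expect_identical(g0$n_og, 0L)
  expect_equal(g0$gamma, 0)

  # empty side: undefined, not zero
  gNA <- gammaConservation(character(0), c("m1"), fam,
                           paste0("h", 1:5), paste0("m", 1:5))
  expect_true(is.na(gNA$gamma))
})

test_that("gamma stays in [0, 1] and is invariant under gene relabeling", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    g1 <- sprintf("h%d", sample(n, n, replace = TRUE))
    g2 <- sprintf("m%d", sample(n, n, replace = TRUE))
    pairs <- unique(data.frame(g1, g2))
    orth <- OrthologyMap(pairs$g1, pairs$g2)
    fam <- buildFamilies(orth)
    a1 <- unique(pairs$g1); a2 <- unique(pairs$g2)
    cm1 <- sample(a1, sample(seq_along(a1), 1))
    cm2 <- sample(a2, sample(seq_along(a2), 1))
    g <- gammaConservation(cm1, cm2, fam, a1, a2)
    if (!is.na(g$gamma)) {
      expect_gte(g$gamma, 0); expect_lte(g$gamma, 1)
      expect_lte(g$n_og, min(g$nfam_h, g$nfam_m))
    }
    # relabel every gene id bijectively
    map1 <- setNames(sprintf("X%d", seq_along(a1)), a1)
    map2 <- setNames(sprintf("Y%d", seq_along(a2)), a2)
    orthR <- OrthologyMap(map1[pairs$g1], map2[pairs$g2])
    gR <- gammaConservation(map1[cm1], map2[cm2], buildFamilies(orthR),
                            map1[a1], map2[a2])
    expect_identical(gR[c("n_og", "nfam_h", "nfam_m")],
                     g[c("n_og", "nfam_h", "nfam_m")])
  }
})

test_that("ortholog reshuffling preserves the pair-class structure", {
  # a single pair has one permutation
  one <- OrthologyMap("h1", "m1")
  expect_identical(orthologPairs(shuffleOrthologs(one)),
                   orthologPairs(one))

  set.seed(14)
  for (rep in 1:10) {
    nO <- sample(10:60, 1); nM <- sample(3:10, 1)
    g1 <- c(sprintf("ho%d", 1:nO), rep(sprintf("hm%d", 1:nM), each = 2))
    g2 <- c(sprintf("mo%d", 1:nO),
            as.vector(vapply(1:nM, function(i)
              sprintf("mm%d_%d", i, 1:2), character(2))))
    orth <- OrthologyMap(g1, g2)
    before <- orthologySummary(orth)
    sh <- shuffleOrthologs(orth)
    after <- orthologySummary(sh)
    expect_identical(after$n_one_to_one, before$n_one_to_one)
    expect_identical(after$n_many_to_many, before$n_many_to_many)
    expect_identical(after$n_pairs, before$n_pairs)
    # per-species degree multisets are preserved
    degs <- function(o) list(sort(table(orthologPairs(o)$gene1)),
                             sort(unname(table(orthologPairs(o)$gene2))))
    expect_identical(degs(sh)[[2]], degs(orth)[[2]])
    expect_identical(degs(sh)[[1]], degs(orth)[[1]])
  }
})

test_that("one-to-one reshuffling is a uniform permutation", {
  orth <- OrthologyMap(sprintf("h%03d", 1:200), sprintf("m%03d", 1:200))
  set.seed(15)
  fixed <- replicate(1000, {
    p <- orthologPairs(shuffleOrthologs(orth))
    mean(p$gene2 == sprintf("m%03d", 1:200))
  })
  # expected fixed-point rate 1/200, se = sqrt(p(1-p)/200)/sqrt(1000)
  se <- sqrt((1 / 200) * (199 / 200) / 200) / sqrt(1000)
  expect_lt(abs(mean(fixed) - 1 / 200), 3 * se)
})

test_that("the shuffled-orthology null sits below the real gamma for conserved modules", {
  # saturation: a co-module spanning the full universe is unchanged by
  # shuffling
  orth <- OrthologyMap(sprintf("h%d", 1:30), sprintf("m%d", 1:30))
  fam <- buildFamilies(orth)
  a1 <- sprintf("h%d", 1:30); a2 <- sprintf("m%d", 1:30)
  real <- gammaConservation(a1, a2, fam, a1, a2)$gamma
  set.seed(16)
  expect_equal(nullGamma(a1, a2, orth, a1, a2, nReps = 5), real)

  # planted conservation (rho = 0.8, 50 one-to-one families in the module)
  set.seed(17)
  wins <- replicate(40, {
    orth <- OrthologyMap(sprintf("h%d", 1:200), sprintf("m%d", 1:200))
    fam <- buildFamilies(orth)
    a1 <- sprintf("h%d", 1:200); a2 <- sprintf("m%d", 1:200)
    cm1 <- sprintf("h%d", 1:50)
    cm2 <- c(sprintf("m%d", 1:40), sprintf("m%d", 151:160))
    real <- gammaConservation(cm1, cm2, fam, a1, a2)$gamma
    null <- nullGamma(cm1, cm2, orth, a1, a2, nReps = 10)
    real > null
  })
  expect_gte(mean(wins), 0.95)
})

test_that("replicate gamma is the probe overlap over the smaller half", {
  expect_equal(replicateGamma(sprintf("p%d", 1:6), sprintf("p%d", 1:6))$gamma, 1)
  expect_equal(replicateGamma(sprintf("p%d", 1:3), sprintf("p%d", 4:6))$gamma, 0)
  r <- replicateGamma(sprintf("p%d", 1:6), sprintf("p%d", 4:8))
  expect_identical(r$n_og, 3L)
  expect_equal(r$gamma, 3 / 5)
})

test_that("the gamma comparison test matches exact enumeration and symmetry", {
  # identical lists: one-sided p = 0.5
  expect_equal(compareGamma(c(0.9, 0.8, 0.7), c(0.9, 0.8, 0.7))$p, 0.5)

  # complete separation of 3 vs 3: exact one-sided p = 1/C(6,3) = 0.05
  res <- compareGamma(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(res$p, 0.05)
  expect_equal(res$U, 9)

  expect_error(compareGamma(numeric(0), c(0.1)), "nonempty")
  expect_error(compareGamma(c(NA_real_), c(0.1)), "nonempty")
})

test_that("simulated conserved gammas separate from shuffled ones", {
  set.seed(18)
  hits <- replicate(40, {
    orth <- OrthologyMap(sprintf("h%d", 1:400), sprintf("m%d", 1:400))
    fam <- buildFamilies(orth)
    a1 <- sprintf("h%d", 1:400); a2 <- sprintf("m%d", 1:400)
    # 40 co-modules with conservation 0.5
    gs <- lapply(1:40, function(i) {
      idx <- sample(400, 20)
      cons <- idx[1:10]
      cm1 <- sprintf("h%d", idx)
      cm2 <- c(sprintf("m%d", cons), sprintf("m%d", sample(setdiff(1:400, idx), 10)))
      list(cm1 = cm1, cm2 = cm2)
    })
    real <- vapply(gs, function(g)
      gammaConservation(g$cm1, g$cm2, fam, a1, a2)$gamma, 0)
    sh <- buildFamilies(shuffleOrthologs(orth))
    null <- vapply(gs, function(g)
      gammaConservation(g$cm1, g$cm2, sh, a1, a2)$gamma, 0)
    compareGamma(real, null)$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("orthology summaries report the one-to-one percentage", {
  orth <- OrthologyMap(c("h1", "h2", "h2", "h3"), c("m1", "m2", "m3", "m4"))
  s <- orthologySummary(orth)
  expect_identical(s$n_pairs, 4L)
  expect_identical(s$n_one_to_one, 2L)   # h1-m1 and h3-m4
  expect_equal(s$pct_one_to_one, 50)
})
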
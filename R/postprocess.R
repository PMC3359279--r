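# Co-module post-processing cascade: (1) redundancy elimination by the
# product of the two species' gene-score correlations, (2) minimum-size
# filter, (3) reduction of fully-overlapping co-modules. Each stage only
# removes co-modules; none is modified.

#' Score-correlation similarity between two co-modules
#'
#' Pearson correlation between the two co-modules' full-length feature-score
#' vectors (zeros for non-members), computed separately per species, and
#' their product. A pair with product above the redundancy cutoff has very
#' similar content in both species. Correlations are undefined when either
#' score vector has zero variance; the product is then reported as 0
#' (non-redundant) with `defined = FALSE`.
#'
#' @param a,b [CoModule-class] objects from the same run (same feature
#'   universes).
#' @return list with `c_h`, `c_m`, `product`, `defined`.
#' @export
pairSimilarity <- function(a, b) {
  s1a <- featureScores(a, 1); s1b <- featureScores(b, 1)
  s2a <- featureScores(a, 2); s2b <- featureScores(b, 2)
  if (!identical(names(s1a), names(s1b)) ||
      !identical(names(s2a), names(s2b)))
    stop("co-modules do not share their feature universes")
  corOrNA <- function(x, y)
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  ch <- corOrNA(s1a, s1b)
  cm <- corOrNA(s2a, s2b)
  defined <- !is.na(ch) && !is.na(cm)
  list(c_h = ch, c_m = cm,
       product = if (defined) ch * cm else 0,
       defined = defined)
}

# deterministic processing order: descending sum of the two feature
# thresholds, then descending total membership, then input order
redundancyOrder <- function(comodules) {
  tsum <- vapply(comodules, function(cm) {
    t <- moduleThresholds(cm)
    t[["feature1"]] + t[["feature2"]]
  }, 0)
  msize <- vapply(comodules, function(cm)
    length(sharedMembers(cm)) + length(featureMembers(cm, 1)) +
      length(featureMembers(cm, 2)), 0L)
  order(-tsum, -msize, seq_along(comodules))
}

#' Eliminate redundant co-modules
#'
#' Greedy procedure: co-modules are visited in order of descending sum of
#' their two feature thresholds (ties: larger total membership, then input
#' order); each is accepted unless its [pairSimilarity()] product with an
#' already-accepted co-module exceeds `productCut`. Of a redundant pair the
#' co-module with the higher threshold sum is therefore kept.
#'
#' @param comodules list of [CoModule-class].
#' @param productCut redundancy cutoff on c_h * c_m (default 0.8).
#' @return accepted co-modules, in their original input order, with a
#'   `removed` attribute naming the input indices that were dropped.
#' @export
eliminateRedundant <- function(comodules, productCut = 0.8) {
  if (length(comodules) <= 1L) return(comodules)
  ord <- redundancyOrder(comodules)
  accepted <- integer(0)
  anyUndefined <- FALSE
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      ps <- pairSimilarity(comodules[[i]], comodules[[j]])
      if (!ps$defined) anyUndefined <- TRUE
      if (ps$product > productCut) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  if (anyUndefined)
    warning("some score correlations were undefined (zero variance); ",
            "treated as non-redundant")
  keep <- sort(accepted)
  out <- comodules[keep]
  attr(out, "removed") <- setdiff(seq_along(comodules), keep)
  out
}

#' Filter out small co-modules
#'
#' Retains co-modules with at least `minCount` features in both species.
#'
#' @param comodules list of [CoModule-class].
#' @param minCount minimum feature (probe set) count per species
#'   (default 10).
#' @return the surviving co-modules, input order preserved.
#' @export
filterMinProbes <- function(comodules, minCount = 10L) {
  keep <- vapply(comodules, function(cm)
    length(featureMembers(cm, 1)) >= minCount &&
      length(featureMembers(cm, 2)) >= minCount, TRUE)
  out <- comodules[keep]
  attr(out, "removed") <- which(!keep)
  out
}

#' Gene-level size of a co-module
#'
#' The size of a co-module is the minimum of its species-1 and species-2
#' gene counts. When a [ProbeGeneMap-class] is supplied, feature memberships
#' are collapsed to unambiguous genes first; otherwise features are counted
#' directly.
#'
#' @param cm a [CoModule-class].
#' @param probeMap optional [ProbeGeneMap-class].
#' @return integer size.
#' @export
comoduleSize <- function(cm, probeMap = NULL) {
  g1 <- featureMembers(cm, 1)
  g2 <- featureMembers(cm, 2)
  if (!is.null(probeMap)) {
    g1 <- collapseProbesToGenes(g1, probeMap)
    g2 <- collapseProbesToGenes(g2, probeMap)
  }
  min(length(g1), length(g2))
}

#' Reduce sets of fully-overlapping co-modules to their largest member
#'
#' Two co-modules have fully overlapping species-1 gene sets when one set
#' contains the other. Within every connected component of this relation the
#' co-module of maximal [comoduleSize()] is kept (ties: larger species-1
#' gene set, then input order) and the rest are discarded.
#'
#' @inheritParams comoduleSize
#' @param comodules list of [CoModule-class].
#' @return the surviving co-modules, input order preserved.
#' @export
reduceFullyOverlapping <- function(comodules, probeMap = NULL) {
  n <- length(comodules)
  if (n <= 1L) return(comodules)
  sets1 <- lapply(comodules, function(cm) {
    g <- featureMembers(cm, 1)
    if (!is.null(probeMap)) g <- collapseProbesToGenes(g, probeMap)
    g
  })
  # union-find over the containment relation
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- sets1[[i]]; b <- sets1[[j]]
    if (all(a %in% b) || all(b %in% a)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  sizes <- vapply(comodules, comoduleSize, 1L, probeMap = probeMap)
  n1 <- lengths(sets1)
  keep <- vapply(split(seq_len(n), comp), function(idx) {
    idx[order(-sizes[idx], -n1[idx], idx)][1L]
  }, 1L)
  keep <- sort(unname(keep))
  out <- comodules[keep]
  attr(out, "removed") <- setdiff(seq_len(n), keep)
  out
}

#' Run the full post-processing cascade
#'
#' Applies, in order: [eliminateRedundant()], [filterMinProbes()],
#' [reduceFullyOverlapping()]. After the cascade no surviving pair has a
#' similarity product above `productCut`, none has fully-overlapping
#' species-1 gene sets, and every survivor has at least `minCount` features
#' in each species.
#'
#' @inheritParams eliminateRedundant
#' @inheritParams filterMinProbes
#' @inheritParams comoduleSize
#' @return the surviving co-modules; attribute `"stages"` records the number
#'   surviving after each stage.
#' @export
postprocessCoModules <- function(comodules, productCut = 0.8,
                                 minCount = 10L, probeMap = NULL) {
  s1 <- eliminateRedundant(comodules, productCut = productCut)
  s2 <- filterMinProbes(s1, minCount = minCount)
  s3 <- reduceFullyOverlapping(s2, probeMap = probeMap)
  attr(s3, "stages") <- c(input = length(comodules), redundancy = length(s1),
                          minimum_size = length(s2), overlap = length(s3))
  s3
}
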
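# Expression-conservation rate gamma and its two reference distributions:
# an orthology-preserving permutation null (reshuffled ortholog pairs) and a
# replicate-split ceiling (co-modules found between two technical-replicate
# halves of one species).
#
# gamma = n_og / min(nfam_h, nfam_m), where n_og counts the gene families
# represented on both species' sides of a co-module (its orthologous
# groups), and nfam_h / nfam_m count the families represented on one side
# whose orthologs are present on the other species' array at all (not
# necessarily in the co-module).

#' Build gene families from an orthology map
#'
#' Gene families are the connected components of the bipartite ortholog
#' graph: genes of both species are vertices and ortholog pairs are edges. A
#' family arising from a one-to-one pair has exactly one member per species.
#' Families are ordered by their smallest member id.
#'
#' @param orth an [OrthologyMap-class].
#' @return A [FamilyPartition-class].
#' @export
buildFamilies <- function(orth) {
  p <- orthologPairs(orth)
  if (nrow(p) == 0L)
    return(new("FamilyPartition", families = list(),
               index1 = integer(0), index2 = integer(0)))
  # species namespaces may collide, so prefix vertex names
  v1 <- paste0("1:", p$gene1)
  v2 <- paste0("2:", p$gene2)
  g <- igraph::graph_from_edgelist(cbind(v1, v2), directed = FALSE)
  comp <- igraph::components(g)
  vn <- igraph::V(g)$name
  fam <- split(vn, comp$membership)
  members <- lapply(fam, function(v) {
    list(species1 = sort(substring(v[startsWith(v, "1:")], 3L)),
         species2 = sort(substring(v[startsWith(v, "2:")], 3L)))
  })
  smallest <- vapply(members, function(m)
    min(c(m$species1, m$species2)), "")
  members <- members[order(smallest)]
  index1 <- integer(0); index2 <- integer(0)
  for (i in seq_along(members)) {
    index1[members[[i]]$species1] <- i
    index2[members[[i]]$species2] <- i
  }
  new("FamilyPartition", families = unname(members),
      index1 = index1, index2 = index2)
}

#' Expression-conservation rate of a co-module
#'
#' Computes gamma = n_og / min(nfam_h, nfam_m) over a family partition:
#' `n_og` counts families with members on both sides of the co-module;
#' `nfam_h` counts families with a member among the species-1 co-module
#' genes and at least one species-2 member present on the species-2 array
#' (not necessarily in the co-module); `nfam_m` is symmetric. gamma is
#' `NA` (undefined, excluded from medians and tests) when the minimum is 0.
#'
#' @param cmGenes1,cmGenes2 character vectors: the co-module's gene-level
#'   memberships per species (probes already collapsed).
#' @param fam a [FamilyPartition-class] from [buildFamilies()].
#' @param arrayGenes1,arrayGenes2 character vectors: all genes measured on
#'   each species' array.
#' @return list with `n_og`, `nfam_h`, `nfam_m`, `gamma`.
#' @examples
#' # one-to-one families f1..f5; co-module holds 4 species-1 genes and 3
#' # species-2 genes, 2 families span both sides: gamma = 2/3
#' orth <- OrthologyMap(paste0("h", 1:5), paste0("m", 1:5))
#' fam <- buildFamilies(orth)
#' gammaConservation(c("h1", "h2", "h3", "h4"), c("m1", "m2", "m5"), fam,
#'                   paste0("h", 1:5), paste0("m", 1:5))
#' @export
gammaConservation <- function(cmGenes1, cmGenes2, fam,
                              arrayGenes1, arrayGenes2) {
  nFam <- length(geneFamilies(fam))
  inCm1 <- famHit(fam@index1, cmGenes1, nFam)
  inCm2 <- famHit(fam@index2, cmGenes2, nFam)
  onArr1 <- famHit(fam@index1, arrayGenes1, nFam)
  onArr2 <- famHit(fam@index2, arrayGenes2, nFam)
  n_og <- sum(inCm1 & inCm2)
  nfam_h <- sum(inCm1 & onArr2)
  nfam_m <- sum(inCm2 & onArr1)
  lo <- min(nfam_h, nfam_m)
  list(n_og = n_og, nfam_h = nfam_h, nfam_m = nfam_m,
       gamma = if (lo > 0) n_og / lo else NA_real_)
}

# logical vector over families: does any of `genes` belong to each family?
famHit <- function(index, genes, nFam) {
  hit <- logical(nFam)
  idx <- index[intersect(genes, names(index))]
  hit[unique(idx)] <- TRUE
  hit
}

#' Reshuffle an ortholog pair list, preserving its one-to-one and
#' many-to-many pair counts
#'
#' Within the one-to-one pairs, species-2 partners are permuted uniformly.
#' Within the many-to-many pairs, the distinct species-2 gene labels
#' involved are relabeled by a uniform random bijection, which preserves the
#' pair multiset structure and hence every gene's pair degree. The output
#' has exactly the same number of one-to-one and many-to-many pairs as the
#' input. Uses R's RNG.
#'
#' @param orth an [OrthologyMap-class].
#' @return A shuffled [OrthologyMap-class].
#' @export
shuffleOrthologs <- function(orth) {
  p <- orthologPairs(orth)
  if (nrow(p) <= 1L) return(orth)
  deg1 <- table(p$gene1)
  deg2 <- table(p$gene2)
  oneToOne <- deg1[p$gene1] == 1L & deg2[p$gene2] == 1L
  g2 <- p$gene2
  if (sum(oneToOne) > 1L)
    g2[oneToOne] <- sample(g2[oneToOne])
  if (sum(!oneToOne) > 0L) {
    labs <- unique(g2[!oneToOne])
    if (length(labs) > 1L) {
      relab <- setNames(sample(labs), labs)
      g2[!oneToOne] <- relab[g2[!oneToOne]]
    }
  }
  OrthologyMap(p$gene1, g2)
}

#' Mean gamma under the reshuffled-orthology null
#'
#' Reshuffles the ortholog list (via [shuffleOrthologs()]), rebuilds the
#' family partition and recomputes gamma, `nReps` times (default 10); the
#' mean over defined values is returned. Undefined replicates are excluded;
#' if all replicates are undefined the result is `NA`.
#'
#' @inheritParams gammaConservation
#' @param orth the real [OrthologyMap-class].
#' @param nReps number of reshuffles.
#' @param details return the per-replicate gamma values as attribute
#'   `"reps"`.
#' @return mean null gamma (numeric scalar, possibly `NA`).
#' @export
nullGamma <- function(cmGenes1, cmGenes2, orth, arrayGenes1, arrayGenes2,
                      nReps = 10L, details = FALSE) {
  stopifnot(nReps >= 1L)
  reps <- vapply(seq_len(nReps), function(i) {
    sh <- shuffleOrthologs(orth)
    gammaConservation(cmGenes1, cmGenes2, buildFamilies(sh),
                      arrayGenes1, arrayGenes2)$gamma
  }, 0)
  out <- if (all(is.na(reps))) NA_real_ else mean(reps, na.rm = TRUE)
  if (details) attr(out, "reps") <- reps
  out
}

#' Replicate-split gamma of a co-module
#'
#' For co-modules found between two technical-replicate halves of a single
#' species, the conservation rate reduces to a probe-set overlap: `n_og` is
#' the number of probe sets present in both halves' memberships, and the
#' family counts are the total probe sets in each half.
#'
#' @param cm a [CoModule-class] from a replicate-split run, or a character
#'   vector of side-1 probe ids.
#' @param side2 character vector of side-2 probe ids (only when `cm` is a
#'   character vector).
#' @return list with `n_og`, `nfam_h`, `nfam_m`, `gamma`.
#' @export
replicateGamma <- function(cm, side2 = NULL) {
  if (is(cm, "CoModule")) {
    a <- featureMembers(cm, 1)
    b <- featureMembers(cm, 2)
  } else {
    a <- cm
    b <- side2
  }
  n_og <- length(intersect(a, b))
  lo <- min(length(a), length(b))
  list(n_og = n_og, nfam_h = length(a), nfam_m = length(b),
       gamma = if (lo > 0) n_og / lo else NA_real_)
}

#' Compare real and null gamma distributions
#'
#' One-sided Mann-Whitney U test of the alternative that the real gamma
#' values are stochastically greater than the null ones. Exact enumeration
#' is used for small untied samples (both sizes below 8); otherwise the
#' normal approximation with tie correction (and no continuity correction)
#' is used. Undefined (NA) gammas are removed first.
#'
#' @param real,null numeric vectors of gamma values.
#' @return list with `U` (the Mann-Whitney statistic for the real sample)
#'   and `p` (one-sided p-value).
#' @export
compareGamma <- function(real, null) {
  real <- real[!is.na(real)]
  null <- null[!is.na(null)]
  if (!length(real) || !length(null))
    stop("both gamma lists must be nonempty after removing undefined values")
  ties <- anyDuplicated(c(real, null)) > 0L
  exact <- length(real) < 8L && length(null) < 8L && !ties
  res <- suppressWarnings(
    wilcox.test(real, null, alternative = "greater",
                exact = exact, correct = FALSE))
  list(U = unname(res$statistic), p = res$p.value)
}

#' Summarize an orthology map
#'
#' Counts pairs, classifies them as one-to-one (both genes occur in exactly
#' one pair) or many-to-many, and reports the one-to-one percentage.
#'
#' @param orth an [OrthologyMap-class].
#' @return list with `n_pairs`, `n_one_to_one`, `n_many_to_many`,
#'   `pct_one_to_one` (0-100 scale), `n_genes1`, `n_genes2`.
#' @export
orthologySummary <- function(orth) {
  p <- orthologPairs(orth)
  if (nrow(p) == 0L)
    return(list(n_pairs = 0L, n_one_to_one = 0L, n_many_to_many = 0L,
                pct_one_to_one = NA_real_, n_genes1 = 0L, n_genes2 = 0L))
  deg1 <- table(p$gene1)
  deg2 <- table(p$gene2)
  o2o <- sum(deg1[p$gene1] == 1L & deg2[p$gene2] == 1L)
  list(n_pairs = nrow(p),
       n_one_to_one = as.integer(o2o),
       n_many_to_many = nrow(p) - as.integer(o2o),
       pct_one_to_one = 100 * o2o / nrow(p),
       n_genes1 = length(deg1), n_genes2 = length(deg2))
}
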
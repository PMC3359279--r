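# Gene-set overlap and attribute-shift statistics: hypergeometric
# over-representation, flat per-term Fisher enrichment, a Wilcoxon rank-sum
# test on dN/dS ratios, and Bonferroni correction.

#' Hypergeometric over-representation of a reference set in a query set
#'
#' Upper-tail (inclusive) hypergeometric test: the probability of observing
#' at least the actual overlap between the query and reference sets when the
#' query is drawn uniformly from the universe.
#'
#' @param query,reference character vectors, both subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @param queryId,referenceId optional labels carried into the result.
#' @return data.frame (one row) with columns query_id, reference_id,
#'   overlap, query_size, reference_size, universe_size, p_raw, p_corrected
#'   (NA until a correction is applied).
#' @export
hypergeometricOverlap <- function(query, reference, universe,
                                  queryId = "query",
                                  referenceId = "reference") {
  query <- unique(query); reference <- unique(reference)
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  if (!all(reference %in% universe))
    stop("reference must be a subset of the universe")
  k <- length(intersect(query, reference))
  m <- length(reference)
  n <- length(universe) - m
  q <- length(query)
  p <- phyper(k - 1L, m, n, q, lower.tail = FALSE)
  data.frame(query_id = queryId, reference_id = referenceId,
             overlap = k, query_size = q, reference_size = m,
             universe_size = length(universe),
             p_raw = p, p_corrected = NA_real_,
             stringsAsFactors = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests and caps at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m number of tests (defaults to `length(p)`).
#' @return corrected p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' Term enrichment by one-sided Fisher test
#'
#' For every term, tests over-representation of the term's annotated genes
#' in `geneSet` from the 2x2 table (in set / not, annotated / not) with a
#' one-sided Fisher exact test, which equals the inclusive upper
#' hypergeometric tail. Flat per-term testing: no ontology-graph
#' decorrelation is attempted. Results are Bonferroni-corrected over
#' `nTests` and sorted by raw p-value.
#'
#' @param geneSet character vector of genes, subset of `universe`.
#' @param annotations named list: term -> character vector of annotated
#'   genes (subsets of `universe`).
#' @param universe character vector of all genes considered.
#' @param nTests number of tests for the Bonferroni correction (defaults to
#'   the number of terms).
#' @return data.frame of [hypergeometricOverlap()] rows, one per term,
#'   sorted by `p_raw`, with `p_corrected` filled in.
#' @export
termEnrichment <- function(geneSet, annotations, universe,
                           nTests = length(annotations)) {
  if (!all(unlist(annotations) %in% universe))
    stop("annotated genes must be a subset of the universe")
  rows <- lapply(names(annotations), function(term)
    hypergeometricOverlap(geneSet, annotations[[term]], universe,
                          queryId = "gene_set", referenceId = term))
  out <- do.call(rbind, rows)
  out$p_corrected <- bonferroni(out$p_raw, m = nTests)
  out[order(out$p_raw), , drop = FALSE]
}

#' Wilcoxon shift test on dN/dS ratios
#'
#' Two-sided Wilcoxon rank-sum test comparing the dN/dS ratios of a
#' co-module's genes against the ratios of all genes in the attribute table
#' (co-module included, as an option the complement can be used instead).
#' Genes without a defined ratio (dS = 0 or missing) are excluded. The
#' direction is "lower" or "higher" by comparing medians. The corrected
#' significance cutoff used downstream defaults to 0.0005 after Bonferroni
#' over `nTests` co-modules.
#'
#' For small problems (`choose(n, n_cm)` at most 20,000) the p-value is an
#' exact, tie-aware enumeration of the rank-sum distribution, two-sided by
#' the distance of the U statistic from its mean; larger problems use the
#' normal approximation of `wilcox.test`.
#'
#' @param cmGenes character vector of co-module gene ids.
#' @param attrs data.frame as from [readGeneAttributes()] (columns gene,
#'   dN, dS, ratio).
#' @param nTests number of tests for the Bonferroni correction (default 98).
#' @param complement compare against the non-co-module genes instead of all
#'   genes.
#' @return list with `median_ratio`, `global_median`, `direction`, `p_raw`,
#'   `p_corrected`, `n_cm`, `n_ref`.
#' @export
dndsShiftTest <- function(cmGenes, attrs, nTests = 98L, complement = FALSE) {
  ok <- !is.na(attrs$ratio)
  cmR <- attrs$ratio[ok & attrs$gene %in% cmGenes]
  refR <- if (complement) attrs$ratio[ok & !(attrs$gene %in% cmGenes)]
          else attrs$ratio[ok]
  if (!length(cmR))
    stop("no co-module gene has a defined dN/dS ratio")
  if (!length(refR))
    stop("reference gene list has no defined dN/dS ratio")
  medCm <- median(cmR)
  medRef <- median(refR)
  n <- length(cmR) + length(refR)
  p <- if (choose(n, length(cmR)) <= 20000)
         exactRankSumP(cmR, refR)
       else suppressWarnings(
         wilcox.test(cmR, refR, exact = FALSE)$p.value)
  list(median_ratio = medCm, global_median = medRef,
       direction = if (medCm < medRef) "lower" else "higher",
       p_raw = p, p_corrected = bonferroni(p, m = nTests),
       n_cm = length(cmR), n_ref = length(refR))
}

# exact two-sided rank-sum p by enumeration of all assignments of the
# pooled values (tie-aware; two-sided via |U - E[U]|)
exactRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (n - n1) / 2
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}
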
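# The Ping-Pong Algorithm (PPA): alternating thresholded projections between
# two expression matrices that share one dimension. Starting from a seed set
# of shared-dimension elements, each cycle projects the current shared scores
# onto dataset 1's features, back onto the shared dimension, onto dataset 2's
# features and back again, thresholding after every projection, until the
# three membership sets stabilize. The surviving fixed points are co-modules.

#' Row- and column-normalize an expression matrix for projection
#'
#' Returns the two z-scored copies the ping-pong projections use: one with
#' each row (feature profile) centered and scaled to unit standard
#' deviation, used when projecting feature scores onto the shared dimension,
#' and one normalized per column (shared-element profile), used when
#' projecting shared scores onto features. Standardizing within the
#' dimension being summed over keeps both projections on a comparable
#' z-score scale. The population (divide-by-n) standard deviation is used
#' throughout. Constant rows or columns are set to all zeros with a warning.
#'
#' @param expr an [ExpressionMatrix-class] or a plain numeric matrix
#'   (features x shared dimension).
#' @return list with elements `row` and `column`, both numeric matrices with
#'   the input's dimnames.
#' @export
normalizeForProjection <- function(expr) {
  v <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else expr
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("need at least 2 rows and 2 columns to normalize")
  zscore <- function(m, margin) {
    mu <- if (margin == 1L) rowMeans(m) else colMeans(m)
    dev <- sweep(m, margin, mu)
    sdv <- sqrt(if (margin == 1L) rowMeans(dev^2) else colMeans(dev^2))
    flat <- sdv == 0
    if (any(flat)) {
      warning(sum(flat), " constant ",
              if (margin == 1L) "row(s)" else "column(s)",
              " set to zero during normalization")
      sdv[flat] <- 1
      dev[if (margin == 1L) flat else TRUE,
          if (margin == 1L) TRUE else flat] <- 0
    }
    sweep(dev, margin, sdv, "/")
  }
  list(row = zscore(v, 1L), column = zscore(v, 2L))
}

#' Threshold a score vector at t standard deviations above its mean
#'
#' Keeps the elements strictly greater than `mean(x) + t * sd(x)` (population
#' standard deviation over the whole input vector) and rescales the survivors
#' by the maximum surviving value, so member scores lie in (0, 1] and
#' non-members are 0. If no element survives -- or the maximum survivor is
#' not positive, so that max-rescaling could not produce scores in (0, 1] --
#' the result is all zeros (empty membership).
#'
#' @param x numeric vector (named or not).
#' @param t nonnegative threshold in standard-deviation units.
#' @return numeric vector of the same length and names as `x`.
#' @examples
#' thresholdScores(c(0, 0, 0, 10), t = 1)  # only the 4th element survives
#' @export
thresholdScores <- function(x, t) {
  stopifnot(t >= 0, length(x) >= 1L)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  keep <- x > m + t * s & x > 0
  out <- numeric(length(x))
  names(out) <- names(x)
  if (any(keep)) out[keep] <- x[keep] / max(x[keep])
  out
}

#' Generate random seed sets over the shared dimension
#'
#' For each seed a size k is drawn uniformly from 1..length(sharedIds) and a
#' uniform k-subset of the shared ids is taken. Uses R's RNG; call
#' `set.seed()` for reproducibility. The default pipeline configuration
#' requests 10,000 seeds.
#'
#' @param sharedIds character vector of shared-dimension ids (HOGs, or
#'   ortholog pairs in the gene-matched run).
#' @param nSeeds number of seeds.
#' @return list of character vectors.
#' @export
makeRandomSeeds <- function(sharedIds, nSeeds) {
  if (length(sharedIds) == 0L) stop("sharedIds must be nonempty")
  if (nSeeds <= 0L) stop("nSeeds must be positive")
  n <- length(sharedIds)
  lapply(seq_len(nSeeds), function(i) {
    k <- sample.int(n, 1L)
    sharedIds[sample.int(n, k)]
  })
}

# shared-dimension alignment check; returns E2 values with columns reordered
# to match E1 when the id sets agree
alignShared <- function(v1, v2) {
  if (!setequal(colnames(v1), colnames(v2)))
    stop("the two matrices do not share their sample dimension")
  v2[, colnames(v1), drop = FALSE]
}

#' Run the ping-pong iteration from one seed
#'
#' Repeats the four-step cycle (dataset-1 features from shared scores,
#' shared from dataset-1 features, dataset-2 features from shared, shared
#' from dataset-2 features; each projection thresholded via
#' [thresholdScores()]) until the three membership sets are identical in two
#' consecutive cycles or the largest absolute score change falls below
#' `tol`. Returns `NULL` when any score vector empties or `maxIter` is
#' reached without convergence.
#'
#' @param E1,E2 [ExpressionMatrix-class] objects sharing their sample
#'   dimension (same ids; columns are aligned automatically).
#' @param seed character vector of shared-dimension ids.
#' @param thresholds numeric of length 3: the z-score cutoffs for dataset-1
#'   features, dataset-2 features, and the shared dimension.
#' @param maxIter maximum number of full cycles.
#' @param tol convergence tolerance on the score vectors.
#' @return A [CoModule-class], or `NULL`.
#' @export
ppaIterate <- function(E1, E2, seed, thresholds, maxIter = 100L, tol = 1e-3) {
  v1 <- exprValues(E1)
  v2 <- alignShared(v1, exprValues(E2))
  n1 <- normalizeForProjection(v1)
  n2 <- normalizeForProjection(v2)
  ppaIterateNorm(n1, n2, colnames(v1), rownames(v1), rownames(v2),
                 seed, thresholds, maxIter, tol)
}

# core runner over precomputed normalized matrices (used by runPPAGrid so
# normalization happens once per run, not once per seed)
ppaIterateNorm <- function(n1, n2, sharedIds, featIds1, featIds2,
                           seed, thresholds, maxIter, tol) {
  if (!all(seed %in% sharedIds))
    stop("seed ids must belong to the shared dimension")
  idx <- match(seed, sharedIds) - 1L
  res <- .ppaFixedPointCpp(n1$row, n1$column, n2$row, n2$column,
                           as.integer(idx),
                           thresholds[[1L]], thresholds[[2L]],
                           thresholds[[3L]],
                           as.integer(maxIter), tol)
  if (!res$converged) return(NULL)
  new("CoModule",
      sharedScores = setNames(res$shared, sharedIds),
      featureScores1 = setNames(res$f1, featIds1),
      featureScores2 = setNames(res$f2, featIds2),
      thresholds = c(feature1 = thresholds[[1L]],
                     feature2 = thresholds[[2L]],
                     shared = thresholds[[3L]]),
      iterations = as.integer(res$iterations),
      converged = TRUE, nSeeds = 1L)
}

#' Apply one ping-pong cycle to a co-module (pure R)
#'
#' Runs the four projection/threshold steps once, starting from the
#' co-module's shared scores. A converged co-module is a fixed point: its
#' membership sets are reproduced exactly. Implemented entirely in R on top
#' of [thresholdScores()], so it doubles as an independent check of the
#' compiled iteration.
#'
#' @inheritParams ppaIterate
#' @param cm a [CoModule-class].
#' @return list with numeric score vectors `f1`, `f2`, `shared`.
#' @export
ppaCycle <- function(E1, E2, cm) {
  v1 <- exprValues(E1)
  v2 <- alignShared(v1, exprValues(E2))
  n1 <- normalizeForProjection(v1)
  n2 <- normalizeForProjection(v2)
  t <- moduleThresholds(cm)
  s <- sharedScores(cm)[colnames(v1)]
  f1 <- thresholdScores(drop(n1$column %*% s), t[["feature1"]])
  s <- thresholdScores(drop(t(n1$row) %*% f1), t[["shared"]])
  f2 <- thresholdScores(drop(n2$column %*% s), t[["feature2"]])
  s <- thresholdScores(drop(t(n2$row) %*% f2), t[["shared"]])
  list(f1 = f1, f2 = f2, shared = s)
}

#' Run the PPA over many seeds and a threshold grid
#'
#' Runs [ppaIterate()] for every combination of seed, feature threshold and
#' shared threshold (the same feature threshold is applied to both
#' datasets), discards non-converged runs, and collapses fixed points with
#' identical membership triples into a single co-module whose `nSeeds` slot
#' counts how many runs reached it. Default grids cover 2.5-6 for features
#' and 1-4.5 for the shared dimension in steps of 0.5.
#'
#' @inheritParams ppaIterate
#' @param seeds list of seeds, e.g. from [makeRandomSeeds()].
#' @param featureGrid numeric vector of feature thresholds.
#' @param sharedGrid numeric vector of shared-dimension thresholds.
#' @return list of distinct converged [CoModule-class] objects.
#' @export
runPPAGrid <- function(E1, E2, seeds,
                       featureGrid = seq(2.5, 6, by = 0.5),
                       sharedGrid = seq(1, 4.5, by = 0.5),
                       maxIter = 100L, tol = 1e-3) {
  stopifnot(length(featureGrid) > 0L, length(sharedGrid) > 0L)
  v1 <- exprValues(E1)
  v2 <- alignShared(v1, exprValues(E2))
  n1 <- normalizeForProjection(v1)
  n2 <- normalizeForProjection(v2)
  sharedIds <- colnames(v1)
  out <- list()
  counts <- integer(0)
  nFail <- 0L
  for (seedSet in seeds) {
    idx <- as.integer(match(seedSet, sharedIds) - 1L)
    if (anyNA(idx)) stop("seed ids must belong to the shared dimension")
    for (tf in featureGrid) for (ts in sharedGrid) {
      res <- .ppaFixedPointCpp(n1$row, n1$column, n2$row, n2$column, idx,
                               tf, tf, ts, as.integer(maxIter), tol)
      if (!res$converged) { nFail <- nFail + 1L; next }
      key <- paste(paste(which(res$shared > 0), collapse = ","),
                   paste(which(res$f1 > 0), collapse = ","),
                   paste(which(res$f2 > 0), collapse = ","), sep = "|")
      if (is.null(out[[key]])) {
        out[[key]] <- new("CoModule",
          sharedScores = setNames(res$shared, sharedIds),
          featureScores1 = setNames(res$f1, rownames(v1)),
          featureScores2 = setNames(res$f2, rownames(v2)),
          thresholds = c(feature1 = tf, feature2 = tf, shared = ts),
          iterations = as.integer(res$iterations),
          converged = TRUE, nSeeds = 1L)
        counts[key] <- 1L
      } else {
        counts[key] <- counts[key] + 1L
      }
    }
  }
  res <- unname(out)
  for (i in seq_along(res)) res[[i]]@nSeeds <- counts[[i]]
  attr(res, "nonconverged") <- nFail
  res
}
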
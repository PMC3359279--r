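#' @import methods
#' @importFrom stats cor median rnorm runif sd wilcox.test fisher.test phyper setNames
#' @importFrom utils read.table write.table head
#' @useDynLib copong, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ExpressionMatrix: a features-by-samples log-scale expression matrix
#'
#' Container for one species' expression data: a numeric matrix whose rows
#' are features (probe sets or genes) and whose columns are samples (organs,
#' homologous organ groups, or per-organ replicates), tagged with a species
#' label. When the columns are technical replicates, `replicateOf` maps each
#' sample id to its organ label so the matrix can be split into two
#' organ-aligned replicate matrices.
#'
#' Values are assumed already on a log-like normalized scale (e.g. the output
#' of array normalization); no normalization is performed by this package.
#'
#' @slot species single character label.
#' @slot values numeric matrix, features x samples, finite, with unique
#'   rownames (feature ids) and colnames (sample ids).
#' @slot replicateOf named character vector mapping sample id -> organ label;
#'   length zero when the design has no replicate structure.
#'
#' @seealso [readExpressionMatrix()], [mergeIntoHOGs()], [splitReplicates()]
#' @export
setClass("ExpressionMatrix",
  representation(species = "character", values = "matrix",
                 replicateOf = "character"),
  prototype(species = NA_character_,
            values = matrix(numeric(0), 0, 0),
            replicateOf = character(0)))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (length(object@species) != 1L)
    msg <- c(msg, "species must be a single label")
  if (!is.numeric(v))
    msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have feature ids as rownames and sample ids as colnames")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, sprintf("duplicated feature id: '%s'",
                            rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, sprintf("duplicated sample id: '%s'",
                            colnames(v)[duplicated(colnames(v))][1L]))
  }
  if (length(v) && !all(is.finite(v)))
    msg <- c(msg, "all expression values must be finite")
  if (length(object@replicateOf)) {
    if (is.null(names(object@replicateOf)))
      msg <- c(msg, "replicateOf must be named by sample id")
    else if (!all(names(object@replicateOf) %in% colnames(v)))
      msg <- c(msg, "replicateOf names must be sample ids of the matrix")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (features x samples) with dimnames.
#' @param species species label.
#' @param replicateOf optional named character vector sample id -> organ.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' ExpressionMatrix(m, species = "mouse")
#' @export
ExpressionMatrix <- function(values, species, replicateOf = character(0)) {
  new("ExpressionMatrix", species = as.character(species),
      values = values, replicateOf = replicateOf)
}

#' HOGMap: homologous organ group assignments
#'
#' Maps (species, sample id) pairs to homologous organ group (HOG) ids.
#' HOGs are groups of anatomically homologous organ samples across the two
#' species and form the shared sample dimension of the organ-matched
#' ping-pong run.
#'
#' @slot entries data.frame with columns `species`, `sample_id`, `hog_id`.
#' @export
setClass("HOGMap", representation(entries = "data.frame"))

setValidity("HOGMap", function(object) {
  e <- object@entries
  if (!all(c("species", "sample_id", "hog_id") %in% names(e)))
    return("entries must have columns species, sample_id, hog_id")
  if (anyDuplicated(e[, c("species", "sample_id")]))
    return("a sample may be assigned to only one HOG per species")
  TRUE
})

#' @rdname HOGMap-class
#' @param species,sample_id,hog_id character vectors of equal length.
#' @return A HOGMap object.
#' @export
HOGMap <- function(species, sample_id, hog_id) {
  new("HOGMap", entries = data.frame(
    species = as.character(species),
    sample_id = as.character(sample_id),
    hog_id = as.character(hog_id),
    stringsAsFactors = FALSE))
}

#' OrthologyMap: cross-species ortholog pair list
#'
#' A set of ortholog pairs between two species. A pair is classified
#' one-to-one when both of its genes participate in exactly one pair;
#' all other pairs are many-to-many.
#'
#' @slot pairs data.frame with columns `gene1` (species 1) and `gene2`
#'   (species 2); no duplicated pairs.
#' @seealso [buildFamilies()], [shuffleOrthologs()], [orthologySummary()]
#' @export
setClass("OrthologyMap", representation(pairs = "data.frame"))

setValidity("OrthologyMap", function(object) {
  p <- object@pairs
  if (!all(c("gene1", "gene2") %in% names(p)))
    return("pairs must have columns gene1, gene2")
  if (anyDuplicated(p[, c("gene1", "gene2")]))
    return("duplicated ortholog pairs are not allowed")
  TRUE
})

#' @rdname OrthologyMap-class
#' @param gene1,gene2 character vectors of gene ids (species 1, species 2).
#' @return An OrthologyMap object.
#' @export
OrthologyMap <- function(gene1, gene2) {
  new("OrthologyMap", pairs = data.frame(
    gene1 = as.character(gene1), gene2 = as.character(gene2),
    stringsAsFactors = FALSE))
}

#' ProbeGeneMap: probe set to gene assignments
#'
#' Maps microarray probe set ids to gene ids. Probes mapping to more than
#' one gene are ambiguous and contribute nothing to gene-level outputs.
#'
#' @slot entries data.frame with columns `probe`, `gene`; multi-gene probes
#'   appear on several rows.
#' @seealso [collapseProbesToGenes()]
#' @export
setClass("ProbeGeneMap", representation(entries = "data.frame"))

setValidity("ProbeGeneMap", function(object) {
  e <- object@entries
  if (!all(c("probe", "gene") %in% names(e)))
    return("entries must have columns probe, gene")
  if (anyDuplicated(e[, c("probe", "gene")]))
    return("duplicated probe-gene rows are not allowed")
  TRUE
})

#' @rdname ProbeGeneMap-class
#' @param probe,gene character vectors of equal length.
#' @return A ProbeGeneMap object.
#' @export
ProbeGeneMap <- function(probe, gene) {
  new("ProbeGeneMap", entries = data.frame(
    probe = as.character(probe), gene = as.character(gene),
    stringsAsFactors = FALSE))
}

#' CoModule: a fixed point of the ping-pong iteration
#'
#' A co-module couples a set of shared-dimension elements (HOGs, or ortholog
#' pairs in the gene-matched run) with one feature set per dataset, all
#' coherently over-expressed. Scores lie in (0, 1] for members and are 0 for
#' non-members; score vectors span the full universe of each dimension so
#' that co-modules from one run are directly comparable.
#'
#' @slot sharedScores named numeric over the shared dimension.
#' @slot featureScores1,featureScores2 named numeric over each dataset's
#'   feature dimension.
#' @slot thresholds numeric of length 3, named `feature1`, `feature2`,
#'   `shared`: the z-score cutoffs that produced this fixed point.
#' @slot iterations number of full ping-pong cycles run.
#' @slot converged logical flag.
#' @slot nSeeds how many (seed, threshold) runs reached this fixed point.
#' @export
setClass("CoModule",
  representation(sharedScores = "numeric",
                 featureScores1 = "numeric",
                 featureScores2 = "numeric",
                 thresholds = "numeric",
                 iterations = "integer",
                 converged = "logical",
                 nSeeds = "integer"),
  prototype(iterations = 0L, converged = FALSE, nSeeds = 1L))

setValidity("CoModule", function(object) {
  msg <- character(0)
  for (nm in c("sharedScores", "featureScores1", "featureScores2")) {
    s <- slot(object, nm)
    if (is.null(names(s))) msg <- c(msg, paste(nm, "must be named"))
    if (length(s) && (any(s < 0) || any(s > 1)))
      msg <- c(msg, paste(nm, "must lie in [0, 1]"))
    if (length(s) && any(s > 0) && !isTRUE(all.equal(max(s), 1)))
      msg <- c(msg, paste(nm, "must have maximum 1 when nonempty"))
  }
  if (!all(c("feature1", "feature2", "shared") %in% names(object@thresholds)))
    msg <- c(msg, "thresholds must be named feature1, feature2, shared")
  if (length(msg)) msg else TRUE
})

#' FamilyPartition: gene families of an orthology map
#'
#' The connected components of the bipartite ortholog graph (genes of both
#' species as vertices, ortholog pairs as edges). A family arising from a
#' one-to-one pair has exactly one member per species; families represented
#' on both sides of a co-module are its orthologous groups.
#'
#' @slot families list; each element a list with character vectors
#'   `species1` and `species2`.
#' @slot index1,index2 named integer vectors mapping gene id -> family index,
#'   per species.
#' @seealso [buildFamilies()], [gammaConservation()]
#' @export
setClass("FamilyPartition",
  representation(families = "list", index1 = "integer", index2 = "integer"))

setValidity("FamilyPartition", function(object) {
  f <- object@families
  g1 <- unlist(lapply(f, `[[`, "species1"))
  g2 <- unlist(lapply(f, `[[`, "species2"))
  if (anyDuplicated(g1) || anyDuplicated(g2))
    return("families must be disjoint")
  TRUE
})
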
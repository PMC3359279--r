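#' @name accessors
#' @title Accessors for copong classes
#' @description Accessor generics for the package's S4 containers. Slot
#'   access via `@` is internal; user code should go through these.
#' @param x an object.
#' @param side which dataset's feature dimension, 1 or 2.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setMethod("featureIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))
#' @rdname accessors
#' @export
setMethod("speciesLabel", "ExpressionMatrix", function(x) x@species)

#' @rdname accessors
#' @export
setGeneric("replicateOf", function(x) standardGeneric("replicateOf"))
#' @rdname accessors
#' @export
setMethod("replicateOf", "ExpressionMatrix", function(x) x@replicateOf)

#' @rdname accessors
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))
#' @rdname accessors
#' @export
setMethod("orthologPairs", "OrthologyMap", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("hogEntries", function(x) standardGeneric("hogEntries"))
#' @rdname accessors
#' @export
setMethod("hogEntries", "HOGMap", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("probeGeneEntries", function(x) standardGeneric("probeGeneEntries"))
#' @rdname accessors
#' @export
setMethod("probeGeneEntries", "ProbeGeneMap", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("sharedScores", function(x) standardGeneric("sharedScores"))
#' @rdname accessors
#' @export
setMethod("sharedScores", "CoModule", function(x) x@sharedScores)

#' @rdname accessors
#' @export
setGeneric("featureScores", function(x, side) standardGeneric("featureScores"))
#' @rdname accessors
#' @export
setMethod("featureScores", "CoModule", function(x, side) {
  side <- match.arg(as.character(side), c("1", "2"))
  if (side == "1") x@featureScores1 else x@featureScores2
})

#' @rdname accessors
#' @export
setGeneric("sharedMembers", function(x) standardGeneric("sharedMembers"))
#' @rdname accessors
#' @export
setMethod("sharedMembers", "CoModule", function(x)
  names(x@sharedScores)[x@sharedScores > 0])

#' @rdname accessors
#' @export
setGeneric("featureMembers", function(x, side) standardGeneric("featureMembers"))
#' @rdname accessors
#' @export
setMethod("featureMembers", "CoModule", function(x, side) {
  s <- featureScores(x, side)
  names(s)[s > 0]
})

#' @rdname accessors
#' @export
setGeneric("moduleThresholds", function(x) standardGeneric("moduleThresholds"))
#' @rdname accessors
#' @export
setMethod("moduleThresholds", "CoModule", function(x) x@thresholds)

#' @rdname accessors
#' @export
setGeneric("geneFamilies", function(x) standardGeneric("geneFamilies"))
#' @rdname accessors
#' @export
setMethod("geneFamilies", "FamilyPartition", function(x) x@families)

setMethod("show", "ExpressionMatrix", function(object) {
  v <- object@values
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples\n",
              object@species, nrow(v), ncol(v)))
  if (length(object@replicateOf))
    cat(sprintf("  replicate design over %d organs\n",
                length(unique(object@replicateOf))))
})

setMethod("show", "CoModule", function(object) {
  cat(sprintf(
    "CoModule: %d shared | %d features (1) | %d features (2); t = (%g, %g, %g); %s in %d cycles; seeds: %d\n",
    sum(object@sharedScores > 0),
    sum(object@featureScores1 > 0),
    sum(object@featureScores2 > 0),
    object@thresholds[["feature1"]], object@thresholds[["feature2"]],
    object@thresholds[["shared"]],
    if (object@converged) "converged" else "not converged",
    object@iterations, object@nSeeds))
})

setMethod("show", "OrthologyMap", function(object) {
  s <- orthologySummary(object)
  cat(sprintf("OrthologyMap: %d pairs (%d one-to-one, %.1f%%; %d many-to-many)\n",
              s$n_pairs, s$n_one_to_one, s$pct_one_to_one, s$n_many_to_many))
})

setMethod("show", "HOGMap", function(object) {
  e <- object@entries
  cat(sprintf("HOGMap: %d samples from %d species onto %d HOGs\n",
              nrow(e), length(unique(e$species)), length(unique(e$hog_id))))
})

setMethod("show", "ProbeGeneMap", function(object) {
  e <- object@entries
  amb <- sum(tabulate(factor(e$probe)) > 1L)
  cat(sprintf("ProbeGeneMap: %d probes -> %d genes (%d ambiguous)\n",
              length(unique(e$probe)), length(unique(e$gene)), amb))
})

setMethod("show", "FamilyPartition", function(object) {
  sizes <- lengths(lapply(object@families, unlist))
  cat(sprintf("FamilyPartition: %d families (%d one-to-one)\n",
              length(object@families), sum(sizes == 2L)))
})
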
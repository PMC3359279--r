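# Readers and writers for the package's plain-text interchange formats, plus
# the sample-level operations on expression matrices: HOG merging, probe ->
# gene collapsing, replicate splitting. All tables are UTF-8 TSV; expression
# matrices carry a header row of sample ids and feature ids in column 1.
# Missing values are not allowed anywhere.

#' Read a tab-separated expression matrix
#'
#' @param path path to a TSV file: header row of sample ids, first column
#'   feature ids, numeric body (log-scale expression).
#' @param species species label to tag the matrix with.
#' @param replicateOf optional named character vector (sample id -> organ).
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, species, replicateOf = character(0)) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("empty or malformed expression file: ", path)
  feat <- tab[[1L]]
  if (anyDuplicated(feat))
    stop("duplicated feature id '", feat[duplicated(feat)][1L], "' in ", path)
  samp <- colnames(tab)[-1L]
  if (anyDuplicated(samp))
    stop("duplicated sample id '", samp[duplicated(samp)][1L], "' in ", path)
  body <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s' in %s",
                 body[bad[1L], bad[2L]], feat[bad[1L]], samp[bad[2L]], path))
  }
  dimnames(num) <- list(feat, samp)
  ExpressionMatrix(num, species = species, replicateOf = replicateOf)
}

#' Write an expression matrix as TSV
#'
#' @param expr an [ExpressionMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(expr, path) {
  v <- exprValues(expr)
  tab <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a homologous-organ-group map
#'
#' @param path 3-column TSV: species, sample_id, hog_id (no header).
#' @return A [HOGMap-class].
#' @export
readHOGMap <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t", quote = "",
                    colClasses = "character",
                    col.names = c("species", "sample_id", "hog_id"))
  HOGMap(tab$species, tab$sample_id, tab$hog_id)
}

#' Read an ortholog pair list
#'
#' @param path 2-column TSV: gene id in species 1, gene id in species 2.
#' @return An [OrthologyMap-class].
#' @export
readOrthologyMap <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t", quote = "",
                    colClasses = "character", col.names = c("gene1", "gene2"))
  OrthologyMap(tab$gene1, tab$gene2)
}

#' Read a probe set to gene map
#'
#' @param path 2-column TSV (probe, gene); multi-gene probes repeat rows.
#' @return A [ProbeGeneMap-class].
#' @export
readProbeGeneMap <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t", quote = "",
                    colClasses = "character", col.names = c("probe", "gene"))
  ProbeGeneMap(tab$probe, tab$gene)
}

#' Read per-gene substitution rates
#'
#' Reads a 3-column TSV (gene, dN, dS) and computes the dN/dS ratio, which
#' is defined only when dS > 0; undefined ratios are NA and excluded from
#' downstream tests.
#'
#' @param path input path.
#' @return data.frame with columns gene, dN, dS, ratio.
#' @export
readGeneAttributes <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t", quote = "",
                    col.names = c("gene", "dN", "dS"),
                    colClasses = c("character", "numeric", "numeric"))
  tab$ratio <- ifelse(tab$dS > 0, tab$dN / tab$dS, NA_real_)
  tab
}

#' Merge organ samples into homologous organ groups
#'
#' Produces one output column per HOG; each cell is the arithmetic mean of
#' that feature's values over the samples mapped to the HOG. Feature order
#' is preserved; HOG columns are ordered by first appearance in the map.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param hogs a [HOGMap-class]; every sample of `expr` must appear under
#'   the matrix's species.
#' @param minSamples HOGs represented by fewer samples than this raise a
#'   warning (arrays in the source design cover each HOG at least twice).
#' @return An [ExpressionMatrix-class] with HOG ids as sample ids.
#' @export
mergeIntoHOGs <- function(expr, hogs, minSamples = 2L) {
  e <- hogEntries(hogs)
  e <- e[e$species == speciesLabel(expr), , drop = FALSE]
  assign <- setNames(e$hog_id, e$sample_id)
  samp <- sampleIds(expr)
  missing <- setdiff(samp, names(assign))
  if (length(missing))
    stop("sample '", missing[1L], "' is not assigned to a HOG")
  grp <- assign[samp]
  hogIds <- unique(e$hog_id[e$sample_id %in% samp])
  nPer <- table(factor(grp, levels = hogIds))
  if (any(nPer < minSamples))
    warning("HOG(s) represented by fewer than ", minSamples, " samples: ",
            paste(names(nPer)[nPer < minSamples], collapse = ", "))
  v <- exprValues(expr)
  merged <- vapply(hogIds, function(h)
    rowMeans(v[, grp == h, drop = FALSE]), numeric(nrow(v)))
  if (nrow(v) == 1L) merged <- matrix(merged, nrow = 1L)
  dimnames(merged) <- list(rownames(v), hogIds)
  ExpressionMatrix(merged, species = speciesLabel(expr))
}

#' Collapse a probe set to its unambiguous gene targets
#'
#' Returns the union of single-gene targets of the unambiguous probes in the
#' set. Probes mapping to more than one gene are ambiguous and contribute
#' nothing; probes absent from the map are ignored (their count is reported
#' via a message).
#'
#' @param features character vector of probe ids.
#' @param map a [ProbeGeneMap-class].
#' @param quiet suppress the unknown-probe message.
#' @return character vector of gene ids.
#' @export
collapseProbesToGenes <- function(features, map, quiet = TRUE) {
  e <- probeGeneEntries(map)
  nGenes <- vapply(split(e$gene, e$probe), function(g) length(unique(g)), 1L)
  unambiguous <- names(nGenes)[nGenes == 1L]
  unknown <- setdiff(features, e$probe)
  if (length(unknown) && !quiet)
    message(length(unknown), " probe(s) absent from the map were ignored")
  keep <- e$probe %in% intersect(features, unambiguous)
  unique(e$gene[keep])
}

#' Split a replicated expression matrix into two organ-aligned matrices
#'
#' Each organ must have exactly two replicate samples; for every organ one
#' replicate is assigned at random to each output. Output columns are
#' labelled by organ so the two matrices are column-paired. Uses R's RNG:
#' call `set.seed()` beforehand for reproducibility.
#'
#' @param expr an [ExpressionMatrix-class] with `replicateOf` set.
#' @return list of two [ExpressionMatrix-class] objects with organ labels as
#'   sample ids; the original sample ids of each half are attached as
#'   attribute `"source_samples"`.
#' @export
splitReplicates <- function(expr) {
  rep <- replicateOf(expr)
  if (!length(rep))
    stop("expression matrix has no replicate structure (replicateOf empty)")
  samp <- sampleIds(expr)
  if (!all(samp %in% names(rep)))
    stop("every sample must have an organ in replicateOf")
  byOrgan <- split(samp, rep[samp])
  bad <- names(byOrgan)[lengths(byOrgan) != 2L]
  if (length(bad))
    stop("organ '", bad[1L], "' does not have exactly 2 replicates")
  organs <- names(byOrgan)
  pick <- runif(length(organs)) < 0.5
  first <- ifelse(pick, vapply(byOrgan, `[`, "", 1L),
                        vapply(byOrgan, `[`, "", 2L))
  second <- ifelse(pick, vapply(byOrgan, `[`, "", 2L),
                         vapply(byOrgan, `[`, "", 1L))
  v <- exprValues(expr)
  mk <- function(cols) {
    m <- v[, cols, drop = FALSE]
    colnames(m) <- organs
    out <- ExpressionMatrix(m, species = speciesLabel(expr))
    attr(out, "source_samples") <- setNames(cols, organs)
    out
  }
  list(mk(first), mk(second))
}
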
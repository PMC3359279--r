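# End-to-end orchestration of the three experiment modes:
#   organ-shared       two species matched through homologous organ groups
#                      (features = probe sets, shared dimension = HOGs)
#   gene-shared        two species matched through one-to-one ortholog pairs
#                      (features = each species' HOGs, shared = gene pairs)
#   replicate-control  one species' technical replicates split into two
#                      organ-aligned matrices (conservation ceiling)
# plus JSON/TSV export of co-modules and the gamma table.

#' Pipeline run configuration
#'
#' Bundles inputs and parameters for [runPipeline()]. Expression inputs may
#' be [ExpressionMatrix-class] objects or TSV paths (read with
#' [readExpressionMatrix()]); maps may be objects or paths likewise.
#' Defaults follow the method's published operating point: 10,000 random
#' seeds, feature thresholds 2.5-6 and shared thresholds 1-4.5 in steps of
#' 0.5, redundancy cutoff 0.8, minimum 10 features per species, 10
#' orthology reshuffles.
#'
#' @param mode one of `"organ-shared"`, `"gene-shared"`,
#'   `"replicate-control"`.
#' @param expr1,expr2 expression inputs (`expr2` unused in replicate mode).
#' @param species1,species2 species labels used when reading from paths.
#' @param hogs [HOGMap-class] or path (organ-shared and gene-shared modes).
#' @param orth [OrthologyMap-class] or path (organ- and gene-shared modes).
#' @param probes [ProbeGeneMap-class] or path (optional; enables gene-level
#'   post-processing and gamma).
#' @param nSeeds number of random seeds.
#' @param featureGrid,sharedGrid threshold grids.
#' @param productCut,minCount post-processing parameters.
#' @param nullReps orthology reshuffles for the null gamma.
#' @param seed RNG seed for the whole run.
#' @param outDir output directory (`NULL` = no files written).
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(mode = c("organ-shared", "gene-shared",
                               "replicate-control"),
                      expr1, expr2 = NULL, species1 = "species1",
                      species2 = "species2", hogs = NULL, orth = NULL,
                      probes = NULL, nSeeds = 10000L,
                      featureGrid = seq(2.5, 6, by = 0.5),
                      sharedGrid = seq(1, 4.5, by = 0.5),
                      productCut = 0.8, minCount = 10L, nullReps = 10L,
                      seed = 1L, outDir = NULL) {
  cfg <- list(mode = match.arg(mode), expr1 = expr1, expr2 = expr2,
              species1 = species1, species2 = species2, hogs = hogs,
              orth = orth, probes = probes, nSeeds = as.integer(nSeeds),
              featureGrid = featureGrid, sharedGrid = sharedGrid,
              productCut = productCut, minCount = as.integer(minCount),
              nullReps = as.integer(nullReps), seed = seed, outDir = outDir)
  if (cfg$mode != "replicate-control" && is.null(cfg$expr2))
    stop("mode '", cfg$mode, "' needs two expression inputs")
  if (cfg$mode != "replicate-control" && is.null(cfg$hogs))
    stop("mode '", cfg$mode, "' needs a HOG map")
  if (cfg$mode == "gene-shared" && is.null(cfg$orth))
    stop("gene-shared mode needs an orthology map")
  class(cfg) <- "RunConfig"
  cfg
}

asExpr <- function(x, species) {
  if (is(x, "ExpressionMatrix")) x else readExpressionMatrix(x, species)
}
asObj <- function(x, reader) {
  if (is.character(x)) reader(x) else x
}

#' Gamma table for a list of co-modules
#'
#' Computes the conservation rate and its reshuffled-orthology null for
#' every co-module. The `nullReps` reshuffled orthologies are drawn once
#' and shared across co-modules. Feature memberships are collapsed to genes
#' through `probeMap` when given.
#'
#' @param comodules list of [CoModule-class].
#' @param orth [OrthologyMap-class].
#' @param arrayGenes1,arrayGenes2 all genes measured per species.
#' @param probeMap optional [ProbeGeneMap-class].
#' @param nullReps number of reshuffles (default 10).
#' @return data.frame with columns co_module_id, n_og, nfam_h, nfam_m,
#'   gamma, null_mean_gamma; attribute `"null_reps"` holds the per-reshuffle
#'   gamma matrix (co-modules x replicates).
#' @export
gammaTable <- function(comodules, orth, arrayGenes1, arrayGenes2,
                       probeMap = NULL, nullReps = 10L) {
  fam <- buildFamilies(orth)
  shuffledFams <- lapply(seq_len(nullReps), function(i)
    buildFamilies(shuffleOrthologs(orth)))
  collapse <- function(feats) {
    if (is.null(probeMap)) feats else collapseProbesToGenes(feats, probeMap)
  }
  rows <- lapply(seq_along(comodules), function(i) {
    g1 <- collapse(featureMembers(comodules[[i]], 1))
    g2 <- collapse(featureMembers(comodules[[i]], 2))
    re <- gammaConservation(g1, g2, fam, arrayGenes1, arrayGenes2)
    nulls <- vapply(shuffledFams, function(sf)
      gammaConservation(g1, g2, sf, arrayGenes1, arrayGenes2)$gamma, 0)
    list(row = data.frame(
           co_module_id = i, n_og = re$n_og, nfam_h = re$nfam_h,
           nfam_m = re$nfam_m, gamma = re$gamma,
           null_mean_gamma = if (all(is.na(nulls))) NA_real_
                             else mean(nulls, na.rm = TRUE)),
         nulls = nulls)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(out, "null_reps") <- do.call(rbind, lapply(rows, `[[`, "nulls"))
  out
}

#' Run the full analysis pipeline
#'
#' Prepares the two matrices for the configured mode, runs the ping-pong
#' grid, applies the post-processing cascade (organ-shared and replicate
#' modes; the gene-matched run keeps only the redundancy elimination, since
#' the minimum-probe-set filter is defined for probe-set features) and
#' computes the gamma table (organ-shared mode: family-based gamma with the
#' reshuffled-orthology null; replicate mode: probe-overlap gamma). When
#' `config$outDir` is set,
#' co-modules are written as JSON and TSV, the gamma table as TSV, and a
#' run log echoing the configuration.
#'
#' Mode preparation: `organ-shared` merges each species' samples into HOGs
#' and restricts both matrices to the HOGs covered by both species.
#' `gene-shared` merges into HOGs, restricts to one-to-one ortholog pairs
#' with expression in both species, picks one probe set per gene at random
#' (seeded) when several match, and transposes so ortholog pairs form the
#' shared dimension. `replicate-control` splits the replicate matrix of one
#' species into two organ-aligned halves at random.
#'
#' @param config a [runConfig()] list.
#' @return list with `comodules` (post-processed), `nRaw` (distinct fixed
#'   points before post-processing), `gamma` (data.frame), `mode`, `stages`
#'   (cascade survivor counts), `config`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  probes <- if (!is.null(config$probes))
    asObj(config$probes, readProbeGeneMap) else NULL

  if (config$mode == "replicate-control") {
    E <- asExpr(config$expr1, config$species1)
    halves <- splitReplicates(E)
    E1 <- halves[[1L]]; E2 <- halves[[2L]]
  } else {
    hogs <- asObj(config$hogs, readHOGMap)
    Ea <- mergeIntoHOGs(asExpr(config$expr1, config$species1), hogs)
    Eb <- mergeIntoHOGs(asExpr(config$expr2, config$species2), hogs)
    shared <- intersect(sampleIds(Ea), sampleIds(Eb))
    if (length(shared) < 2L)
      stop("fewer than 2 HOGs are covered by both species")
    Ea <- ExpressionMatrix(exprValues(Ea)[, shared, drop = FALSE],
                           speciesLabel(Ea))
    Eb <- ExpressionMatrix(exprValues(Eb)[, shared, drop = FALSE],
                           speciesLabel(Eb))
    if (config$mode == "organ-shared") {
      E1 <- Ea; E2 <- Eb
    } else {
      prep <- geneSharedMatrices(Ea, Eb, asObj(config$orth, readOrthologyMap),
                                 probes)
      E1 <- prep$E1; E2 <- prep$E2
    }
  }

  seeds <- makeRandomSeeds(sampleIds(E1), config$nSeeds)
  raw <- runPPAGrid(E1, E2, seeds, featureGrid = config$featureGrid,
                    sharedGrid = config$sharedGrid)
  if (config$mode == "gene-shared") {
    # the filtering cascade is defined for probe-set features; in the
    # gene-matched run the feature dimensions are the species' organs, so
    # only the redundancy elimination applies
    post <- eliminateRedundant(raw, productCut = config$productCut)
    attr(post, "stages") <- c(input = length(raw), redundancy = length(post))
  } else {
    post <- postprocessCoModules(raw, productCut = config$productCut,
                                 minCount = config$minCount,
                                 probeMap = probes)
  }

  if (config$mode == "replicate-control") {
    gam <- do.call(rbind, lapply(seq_along(post), function(i) {
      r <- replicateGamma(post[[i]])
      data.frame(co_module_id = i, n_og = r$n_og, nfam_h = r$nfam_h,
                 nfam_m = r$nfam_m, gamma = r$gamma,
                 null_mean_gamma = NA_real_)
    }))
  } else if (config$mode == "organ-shared" && !is.null(config$orth)) {
    orth <- asObj(config$orth, readOrthologyMap)
    if (is.null(probes)) {
      ag1 <- featureIds(E1); ag2 <- featureIds(E2)
    } else {
      ag1 <- collapseProbesToGenes(featureIds(E1), probes)
      ag2 <- collapseProbesToGenes(featureIds(E2), probes)
    }
    gam <- gammaTable(post, orth, ag1, ag2, probeMap = probes,
                      nullReps = config$nullReps)
  } else {
    gam <- NULL
  }

  out <- list(comodules = post, nRaw = length(raw), gamma = gam,
              mode = config$mode, stages = attr(post, "stages"),
              config = config)
  if (!is.null(config$outDir)) writeRunOutputs(out, config$outDir)
  out
}

# gene-shared preparation: one-to-one pairs, one probe per gene, transpose
geneSharedMatrices <- function(Ea, Eb, orth, probes) {
  p <- orthologPairs(orth)
  deg1 <- table(p$gene1); deg2 <- table(p$gene2)
  o2o <- p[deg1[p$gene1] == 1L & deg2[p$gene2] == 1L, , drop = FALSE]
  pickProbe <- function(E, genes) {
    if (is.null(probes)) return(setNames(genes, genes))
    e <- probeGeneEntries(probes)
    e <- e[e$probe %in% featureIds(E) & e$gene %in% genes, , drop = FALSE]
    picked <- vapply(split(e$probe, e$gene), function(pp)
      if (length(pp) == 1L) pp else sample(pp, 1L), "")
    picked
  }
  pr1 <- pickProbe(Ea, o2o$gene1)
  pr2 <- pickProbe(Eb, o2o$gene2)
  keep <- o2o$gene1 %in% names(pr1) & o2o$gene2 %in% names(pr2) &
    pr1[o2o$gene1] %in% featureIds(Ea) & pr2[o2o$gene2] %in% featureIds(Eb)
  o2o <- o2o[keep, , drop = FALSE]
  if (nrow(o2o) < 2L)
    stop("fewer than 2 one-to-one ortholog pairs with expression data")
  pairIds <- paste(o2o$gene1, o2o$gene2, sep = "|")
  m1 <- t(exprValues(Ea)[pr1[o2o$gene1], , drop = FALSE])
  m2 <- t(exprValues(Eb)[pr2[o2o$gene2], , drop = FALSE])
  colnames(m1) <- colnames(m2) <- pairIds
  rownames(m1) <- paste0(speciesLabel(Ea), ":", rownames(m1))
  rownames(m2) <- paste0(speciesLabel(Eb), ":", rownames(m2))
  list(E1 = ExpressionMatrix(m1, speciesLabel(Ea)),
       E2 = ExpressionMatrix(m2, speciesLabel(Eb)))
}

#' Write co-modules as a JSON document
#'
#' One JSON list with one record per co-module: ids, member scores (4
#' decimal places), thresholds, iteration count and seed-provenance count.
#'
#' @param comodules list of [CoModule-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCoModulesJSON <- function(comodules, path) {
  memb <- function(s) {
    keep <- s > 0
    list(ids = names(s)[keep], scores = round(unname(s[keep]), 4L))
  }
  doc <- lapply(seq_along(comodules), function(i) {
    cm <- comodules[[i]]
    t <- moduleThresholds(cm)
    list(co_module_id = i,
         thresholds = list(feature1 = t[["feature1"]],
                           feature2 = t[["feature2"]],
                           shared = t[["shared"]]),
         iterations = cm@iterations, n_seeds = cm@nSeeds,
         shared = memb(sharedScores(cm)),
         features1 = memb(featureScores(cm, 1)),
         features2 = memb(featureScores(cm, 2)))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write co-module memberships as a flat TSV
#'
#' Long format: one row per (co-module, dimension, member) with its score.
#' Dimensions are `shared`, `features1`, `features2`.
#'
#' @inheritParams writeCoModulesJSON
#' @return `path`, invisibly.
#' @export
writeCoModulesTSV <- function(comodules, path) {
  rows <- lapply(seq_along(comodules), function(i) {
    cm <- comodules[[i]]
    one <- function(s, dim) {
      keep <- s > 0
      if (!any(keep)) return(NULL)
      data.frame(co_module_id = i, dimension = dim,
                 element_id = names(s)[keep],
                 score = round(unname(s[keep]), 4L))
    }
    rbind(one(sharedScores(cm), "shared"),
          one(featureScores(cm, 1), "features1"),
          one(featureScores(cm, 2), "features2"))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(co_module_id = integer(0), dimension = character(0),
                      element_id = character(0), score = numeric(0))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

writeRunOutputs <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeCoModulesJSON(result$comodules, file.path(outDir, "comodules.json"))
  writeCoModulesTSV(result$comodules, file.path(outDir, "comodules.tsv"))
  if (!is.null(result$gamma))
    write.table(result$gamma, file.path(outDir, "gamma.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  cfg <- result$config
  log <- c(sprintf("mode: %s", result$mode),
           sprintf("seed: %s", cfg$seed),
           sprintf("n_seeds: %d", cfg$nSeeds),
           sprintf("feature_grid: %s", paste(cfg$featureGrid, collapse = ",")),
           sprintf("shared_grid: %s", paste(cfg$sharedGrid, collapse = ",")),
           sprintf("product_cut: %g", cfg$productCut),
           sprintf("min_count: %d", cfg$minCount),
           sprintf("null_reps: %d", cfg$nullReps),
           sprintf("distinct_fixed_points: %d", result$nRaw),
           sprintf("surviving_comodules: %d", length(result$comodules)),
           sprintf("stage_counts: %s",
                   paste(names(result$stages), result$stages, sep = "=",
                         collapse = ", ")))
  writeLines(log, file.path(outDir, "run.log"))
  invisible(outDir)
}
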
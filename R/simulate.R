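# Paired-species synthetic expression data with planted, partially
# conserved co-modules. The generator emulates the structure the analysis
# assumes: HOG-merged log-scale matrices with per-organ technical
# replicates, one-to-one and many-to-many ortholog families, multi-probe
# genes, and a configurable conservation fraction rho (the proportion of a
# planted module's species-1 genes whose orthologs are planted on side 2;
# the remainder of side 2 is filled from non-planted families so that the
# conservation measured on the planted truth equals rho by construction).

#' Configuration for the synthetic paired-species generator
#'
#' Defaults describe the simulation testbed used throughout the package's
#' validation: 12 HOGs sampled twice per species, 200 gene families of which
#' 86.6% are one-to-one, 3 planted modules of 12 genes spanning 3 HOGs
#' each, a 5 sigma over-expression effect on unit Gaussian noise, technical
#' replicate noise at half the biological noise, and conservation fraction
#' 0.8. Modules are kept to a few percent of the feature universe and to
#' small organ sets, mirroring the organ-specific modules of real expression
#' atlases and keeping the default threshold grids informative.
#'
#' @param nHogs number of homologous organ groups.
#' @param samplesPerHog technical replicates per HOG per species.
#' @param nFamilies number of gene families per species pair.
#' @param fractionOneToOne proportion of families that are one-to-one;
#'   exactly `round(fractionOneToOne * nFamilies)` are generated.
#' @param maxFamilySize maximum genes per species in a many-to-many family.
#' @param probesPerGeneProbs named numeric: probability of a gene having
#'   1, 2, ... probe sets.
#' @param nPlanted number of planted co-modules.
#' @param organsPerModule integer range (length 2) of HOGs per module.
#' @param genesPerModule genes per module and species.
#' @param conservationRho proportion of a module's species-1 genes whose
#'   orthologs are planted on side 2.
#' @param effectDelta over-expression shift in units of `noiseSd`.
#' @param noiseSd baseline (biological) standard deviation.
#' @param techSd technical replicate standard deviation.
#' @param seed RNG seed (`NULL` = use the current RNG state).
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nHogs = 12L, samplesPerHog = 2L, nFamilies = 200L,
                      fractionOneToOne = 0.866, maxFamilySize = 3L,
                      probesPerGeneProbs = c(`1` = 0.8, `2` = 0.15, `3` = 0.05),
                      nPlanted = 3L, organsPerModule = c(3L, 3L),
                      genesPerModule = 12L, conservationRho = 0.8,
                      effectDelta = 5, noiseSd = 1, techSd = 0.5,
                      seed = NULL) {
  cfg <- list(nHogs = as.integer(nHogs),
              samplesPerHog = as.integer(samplesPerHog),
              nFamilies = as.integer(nFamilies),
              fractionOneToOne = fractionOneToOne,
              maxFamilySize = as.integer(maxFamilySize),
              probesPerGeneProbs = probesPerGeneProbs,
              nPlanted = as.integer(nPlanted),
              organsPerModule = as.integer(organsPerModule),
              genesPerModule = as.integer(genesPerModule),
              conservationRho = conservationRho,
              effectDelta = effectDelta, noiseSd = noiseSd, techSd = techSd,
              seed = seed)
  stopifnot(cfg$nHogs > 0L, cfg$samplesPerHog > 0L, cfg$nFamilies > 0L,
            cfg$fractionOneToOne >= 0, cfg$fractionOneToOne <= 1,
            cfg$maxFamilySize >= 1L, all(cfg$probesPerGeneProbs >= 0),
            cfg$nPlanted >= 0L, length(cfg$organsPerModule) == 2L,
            cfg$genesPerModule > 0L,
            cfg$conservationRho >= 0, cfg$conservationRho <= 1,
            cfg$effectDelta >= 0, cfg$noiseSd > 0, cfg$techSd >= 0)
  class(cfg) <- "SimConfig"
  cfg
}

# family/probe scaffolding shared by both generators
simScaffold <- function(cfg) {
  nOne <- round(cfg$fractionOneToOne * cfg$nFamilies)
  nMany <- cfg$nFamilies - nOne
  gid <- function(prefix, i) sprintf("%s%04d", prefix, i)
  fam <- vector("list", cfg$nFamilies)
  g1 <- g2 <- 0L
  pairs1 <- character(0); pairs2 <- character(0)
  for (i in seq_len(cfg$nFamilies)) {
    if (i <= nOne) {
      s1 <- 1L; s2 <- 1L
    } else {
      repeat {
        s1 <- sample.int(cfg$maxFamilySize, 1L)
        s2 <- sample.int(cfg$maxFamilySize, 1L)
        if (s1 > 1L || s2 > 1L) break
      }
    }
    m1 <- gid("h", g1 + seq_len(s1)); g1 <- g1 + s1
    m2 <- gid("m", g2 + seq_len(s2)); g2 <- g2 + s2
    fam[[i]] <- list(species1 = m1, species2 = m2)
    grid <- expand.grid(m1, m2, stringsAsFactors = FALSE)
    pairs1 <- c(pairs1, grid[[1L]]); pairs2 <- c(pairs2, grid[[2L]])
  }
  nProbes <- as.integer(names(cfg$probesPerGeneProbs))
  drawProbes <- function(genes) {
    k <- sample(nProbes, length(genes), replace = TRUE,
                prob = cfg$probesPerGeneProbs)
    probe <- unlist(mapply(function(g, n) paste0(g, "_p", seq_len(n)),
                           genes, k, SIMPLIFY = FALSE), use.names = FALSE)
    gene <- rep(genes, k)
    data.frame(probe = probe, gene = gene, stringsAsFactors = FALSE)
  }
  genes1 <- unlist(lapply(fam, `[[`, "species1"), use.names = FALSE)
  genes2 <- unlist(lapply(fam, `[[`, "species2"), use.names = FALSE)
  pg1 <- drawProbes(genes1)
  pg2 <- drawProbes(genes2)
  list(families = fam, nOne = nOne,
       orth = OrthologyMap(pairs1, pairs2),
       genes1 = genes1, genes2 = genes2, pg1 = pg1, pg2 = pg2)
}

# choose planted hog sets (disjoint) and planted gene sets (disjoint,
# one-to-one families only, fillers from unused one-to-one families)
simPlant <- function(cfg, sc) {
  hogIds <- sprintf("HOG%02d", seq_len(cfg$nHogs))
  sizeRange <- seq.int(cfg$organsPerModule[1L], cfg$organsPerModule[2L])
  sizes <- if (length(sizeRange) == 1L) rep(sizeRange, cfg$nPlanted)
           else sample(sizeRange, cfg$nPlanted, replace = TRUE)
  if (sum(sizes) > cfg$nHogs)
    stop("infeasible config: planted modules need more HOGs than exist")
  g <- cfg$genesPerModule
  nCons <- round(cfg$conservationRho * g)
  needFam <- cfg$nPlanted * (2L * g - nCons)
  if (needFam > sc$nOne)
    stop("infeasible config: planted modules need more one-to-one families ",
         "than exist")
  onePool <- sample(seq_len(sc$nOne))  # family indices 1..nOne are 1:1
  hogPool <- sample(hogIds)
  modules <- vector("list", cfg$nPlanted)
  fOff <- 0L; hOff <- 0L
  for (k in seq_len(cfg$nPlanted)) {
    hogs <- sort(hogPool[hOff + seq_len(sizes[k])]); hOff <- hOff + sizes[k]
    famIdx <- onePool[fOff + seq_len(g)]; fOff <- fOff + g
    fillIdx <- onePool[fOff + seq_len(g - nCons)]; fOff <- fOff + g - nCons
    consIdx <- famIdx[seq_len(nCons)]
    genes1 <- vapply(sc$families[famIdx], function(f) f$species1, "")
    genes2 <- c(vapply(sc$families[consIdx], function(f) f$species2, ""),
                vapply(sc$families[fillIdx], function(f) f$species2, ""))
    modules[[k]] <- list(
      hogs = hogs, genes1 = genes1, genes2 = sort(genes2),
      probes1 = sc$pg1$probe[sc$pg1$gene %in% genes1],
      probes2 = sc$pg2$probe[sc$pg2$gene %in% genes2],
      conservedGenes1 = vapply(sc$families[consIdx],
                               function(f) f$species1, ""))
  }
  list(hogIds = hogIds, modules = modules)
}

# biological signal matrix (probes x hogs) with planted over-expression,
# then replicate sampling
simBioMatrix <- function(cfg, probes, hogIds, modules, side) {
  bio <- matrix(rnorm(length(probes) * length(hogIds), sd = cfg$noiseSd),
                length(probes), length(hogIds),
                dimnames = list(probes, hogIds))
  for (m in modules) {
    p <- if (side == 1L) m$probes1 else m$probes2
    bio[p, m$hogs] <- bio[p, m$hogs] + cfg$effectDelta * cfg$noiseSd
  }
  bio
}

simReplicates <- function(cfg, bio, species) {
  cols <- lapply(seq_len(cfg$samplesPerHog), function(r)
    bio + matrix(rnorm(length(bio), sd = cfg$techSd),
                 nrow(bio), ncol(bio)))
  v <- do.call(cbind, cols)
  samp <- as.vector(vapply(seq_len(cfg$samplesPerHog), function(r)
    paste0(colnames(bio), "_r", r), character(ncol(bio))))
  colnames(v) <- samp
  organ <- rep(colnames(bio), cfg$samplesPerHog)
  ExpressionMatrix(v, species = species,
                   replicateOf = setNames(organ, samp))
}

#' Simulate a paired-species expression data set with planted co-modules
#'
#' Generates two replicate-level expression matrices, the HOG map, the
#' orthology, the probe-gene map and the planted truth, per the
#' configuration. Baseline values are independent Gaussians; planted
#' module probes gain `effectDelta * noiseSd` in their module's HOGs;
#' replicate columns add independent technical noise. Fully reproducible
#' from `config$seed`.
#'
#' @param config a [simConfig()] list.
#' @return list with elements `E1`, `E2` ([ExpressionMatrix-class] at
#'   replicate level), `hogs` ([HOGMap-class]), `orth`
#'   ([OrthologyMap-class]), `probes` ([ProbeGeneMap-class], both species),
#'   and `truth` (list with `modules`, each holding `hogs`, `genes1`,
#'   `genes2`, `probes1`, `probes2`, `conservedGenes1`).
#' @export
simulatePair <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sc <- simScaffold(config)
  pl <- simPlant(config, sc)
  bio1 <- simBioMatrix(config, sc$pg1$probe, pl$hogIds, pl$modules, 1L)
  bio2 <- simBioMatrix(config, sc$pg2$probe, pl$hogIds, pl$modules, 2L)
  E1 <- simReplicates(config, bio1, "species1")
  E2 <- simReplicates(config, bio2, "species2")
  hogTab <- rbind(
    data.frame(species = "species1", sample_id = sampleIds(E1),
               hog_id = replicateOf(E1)[sampleIds(E1)]),
    data.frame(species = "species2", sample_id = sampleIds(E2),
               hog_id = replicateOf(E2)[sampleIds(E2)]))
  pg <- rbind(sc$pg1, sc$pg2)
  list(E1 = E1, E2 = E2,
       hogs = HOGMap(hogTab$species, hogTab$sample_id, hogTab$hog_id),
       orth = sc$orth,
       probes = ProbeGeneMap(pg$probe, pg$gene),
       truth = list(modules = pl$modules,
                    arrayGenes1 = sc$genes1, arrayGenes2 = sc$genes2))
}

#' Simulate one species' replicate pair
#'
#' Generates the two technical-replicate matrices of a single species
#' (identical planted biology, independent technical noise), organ-aligned
#' by column, for estimating the replicate-split conservation ceiling.
#' Requires `samplesPerHog = 2`.
#'
#' @param config a [simConfig()] list.
#' @return list with `Ea`, `Eb` ([ExpressionMatrix-class], columns = HOGs)
#'   and `truth` (modules with `hogs`, `genes1`, `probes1`, `probes2` --
#'   the latter equal to `probes1`, both halves share the probe universe).
#' @export
simulateReplicatePair <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$samplesPerHog != 2L)
    stop("replicate-pair simulation requires samplesPerHog = 2")
  if (!is.null(config$seed)) set.seed(config$seed)
  sc <- simScaffold(config)
  pl <- simPlant(config, sc)
  bio <- simBioMatrix(config, sc$pg1$probe, pl$hogIds, pl$modules, 1L)
  noise <- function() matrix(rnorm(length(bio), sd = config$techSd),
                             nrow(bio), ncol(bio), dimnames = dimnames(bio))
  Ea <- ExpressionMatrix(bio + noise(), species = "species1")
  Eb <- ExpressionMatrix(bio + noise(), species = "species1")
  modules <- lapply(pl$modules, function(m) {
    m$probes2 <- m$probes1
    m$genes2 <- m$genes1
    m
  })
  list(Ea = Ea, Eb = Eb,
       truth = list(modules = modules, arrayGenes1 = sc$genes1,
                    arrayGenes2 = sc$genes1))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Best-match recovery of planted modules
#'
#' Matches every planted module to the found co-module maximizing the mean
#' Jaccard index across the organ dimension and the two feature dimensions;
#' unmatched planted modules (empty `found`) score 0.
#'
#' @param truth the `truth` element of [simulatePair()] /
#'   [simulateReplicatePair()] output.
#' @param found list of [CoModule-class].
#' @return data.frame with one row per planted module: `organ_jaccard`,
#'   `gene1_jaccard`, `gene2_jaccard`, `mean_jaccard`, `matched` (index into
#'   `found`, NA when `found` is empty).
#' @export
recoveryScore <- function(truth, found) {
  rows <- lapply(seq_along(truth$modules), function(k) {
    m <- truth$modules[[k]]
    if (!length(found))
      return(data.frame(module = k, organ_jaccard = 0, gene1_jaccard = 0,
                        gene2_jaccard = 0, mean_jaccard = 0, matched = NA))
    js <- vapply(found, function(cm) {
      j <- c(jaccard(m$hogs, sharedMembers(cm)),
             jaccard(m$probes1, featureMembers(cm, 1)),
             jaccard(m$probes2, featureMembers(cm, 2)))
      c(j, mean(j))
    }, numeric(4L))
    best <- which.max(js[4L, ])
    data.frame(module = k, organ_jaccard = js[1L, best],
               gene1_jaccard = js[2L, best], gene2_jaccard = js[3L, best],
               mean_jaccard = js[4L, best], matched = best)
  })
  do.call(rbind, rows)
}
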
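# copong

Cross-species co-module discovery and expression-conservation statistics
via the Ping-Pong Algorithm (PPA).

## What it is for

Comparing organ-level gene expression between two species (say, mouse and
human microarray atlases) runs into a basic obstacle: most genes say
nothing about organ identity, so global correlation or distance measures
between expression profiles dilute the signal of the organ-specific
minority. `copong` is for researchers who want the modular alternative: it
simultaneously biclusters two expression matrices that share one dimension
and extracts **co-modules** — a set of shared elements (homologous organ
groups, or one-to-one ortholog pairs) together with one gene set per
species, all coherently over-expressed — and then asks, per co-module, how
conserved expression is between the species.

## The method in brief

Each species contributes a features × shared matrix *E*. With *E⁽ᶜ⁾* the
column-z-scored and *E⁽ʳ⁾* the row-z-scored copy (population sd), the
ping-pong iteration alternates thresholded projections

&nbsp;&nbsp;*f₁* = θ<sub>t_f</sub>(E₁⁽ᶜ⁾ s),&nbsp;
*s* = θ<sub>t_s</sub>(E₁⁽ʳ⁾ᵀ f₁),&nbsp;
*f₂* = θ<sub>t_f</sub>(E₂⁽ᶜ⁾ s),&nbsp;
*s* = θ<sub>t_s</sub>(E₂⁽ʳ⁾ᵀ f₂)

until the three membership sets stabilize, where θ<sub>t</sub> keeps
entries above mean + *t*·sd of the vector and rescales survivors to
(0, 1]. Thousands of random seed sets and a grid of thresholds
(features 2.5–6, shared dimension 1–4.5) are run; distinct fixed points
are the co-modules. A three-stage cascade then removes redundant
co-modules (score-correlation product > 0.8 keeps the sharper variant),
small ones (< 10 probe sets in either species), and fully-overlapping ones
(nested species-1 gene sets keep the biggest).

Conservation of a co-module with gene sets *G₁*, *G₂* is

&nbsp;&nbsp;γ = n<sub>og</sub> / min(nfam<sub>h</sub>, nfam<sub>m</sub>),

counting gene families (connected components of the bipartite ortholog
graph) present on both sides versus families present on one side with
orthologs on the other species' array at all. γ is calibrated against an
orthology reshuffle that preserves the one-to-one / many-to-many pair
counts, and against a replicate-split ceiling (the same engine run on two
technical-replicate halves of one species). Hypergeometric overlap, flat
Fisher term enrichment, Bonferroni correction and a Wilcoxon dN/dS shift
test cover the downstream statistics. A synthetic paired-species generator
with planted, partially conserved co-modules provides ground truth for all
of it.

## Worked example

Simulate a paired-species data set with three planted co-modules
(conservation fraction 0.8), run the grid, post-process, and score
conservation against the reshuffled-orthology null:

```r
library(copong)

sim <- simulatePair(simConfig(seed = 7))
E_h <- mergeIntoHOGs(sim$E1, sim$hogs)
E_m <- mergeIntoHOGs(sim$E2, sim$hogs)
E_h
#> ExpressionMatrix [species1]: 275 features x 12 samples

set.seed(7)
seeds <- makeRandomSeeds(sampleIds(E_h), 200)
raw <- runPPAGrid(E_h, E_m, seeds)
length(raw)          # distinct fixed points across 200 seeds x 64 threshold pairs
#> [1] 24

post <- postprocessCoModules(raw, probeMap = sim$probes)
attr(post, "stages")
#>        input   redundancy minimum_size      overlap
#>           24           19            3            3
post[[1]]
#> CoModule: 3 shared | 13 features (1) | 15 features (2); t = (3, 3, 1); converged in 3 cycles; seeds: 116

genes_h <- collapseProbesToGenes(featureIds(E_h), sim$probes)
genes_m <- collapseProbesToGenes(featureIds(E_m), sim$probes)
gt <- gammaTable(post, sim$orth, genes_h, genes_m,
                 probeMap = sim$probes, nullReps = 10)
gt
#>   co_module_id n_og nfam_h nfam_m     gamma null_mean_gamma
#> 1            1   10     12     12 0.8333333      0.05000000
#> 2            2    6      9     10 0.6666667      0.08888889
#> 3            3    6     10      8 0.7500000      0.03750000

compareGamma(gt$gamma, as.vector(attr(gt, "null_reps")))$p
#> [1] 0.001418931

recoveryScore(sim$truth, raw)[, 1:4]
#>   module organ_jaccard gene1_jaccard gene2_jaccard
#> 1      1             1             1             1
#> 2      2             1             1             1
#> 3      3             1             1             1
```

Reading the numbers: the 24 raw fixed points collapse to 3 surviving
co-modules — one per planted module (the raw grid recovers every planted
organ and gene set exactly here, `recoveryScore` all 1s). Their γ of
0.67–0.83 sits near the planted conservation fraction 0.8 (the
post-processing keeps sharpened variants, so memberships are conservative
subsets), while the reshuffled-orthology null stays below 0.09; the
one-sided Mann-Whitney p of 0.0014 says the conservation signal is far
from chance.

The full pipeline (HOG merging, mode dispatch for the organ-matched,
gene-matched and replicate-control experiments, JSON/TSV export) is driven
by `runPipeline(runConfig(...))`; see `?runPipeline` and the methods
vignette in `vignettes/copong-methods.Rmd`.

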
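---
title: "Cross-species co-module discovery and expression conservation with copong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species co-module discovery and expression conservation with copong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copong)
```

## The problem

Whether organ-specific gene expression is conserved between species is hard
to read off global similarity measures: most genes are uninformative about
organ identity, and correlations computed across all genes dilute whatever
signal the organ-specific minority carries. `copong` takes the modular
route. It searches two expression matrices that share one dimension --
homologous organ groups (HOGs), or one-to-one ortholog pairs -- for
*co-modules*: a set of shared-dimension elements together with one gene
set per species, all coherently over-expressed. Conservation is then
quantified per co-module, not per gene.

## The ping-pong iteration

Each species contributes a features x shared matrix $E$ (log-scale
expression; probe sets x HOGs in the organ-matched run). Two z-scored
copies of each matrix are kept, using the population (divide-by-$n$)
standard deviation throughout:

* $E^{(c)}$, normalized within each shared-dimension column: the entry for
  feature $g$ in column $o$ says how high $g$ sits in $o$ relative to all
  features. Feature scores are the thresholded projection
  $f = \theta_{t_f}(E^{(c)} s)$ of the current shared scores $s$.
* $E^{(r)}$, normalized within each feature row: the entry says how
  specific $o$ is within $g$'s profile. Shared scores are
  $s = \theta_{t_s}(E^{(r)\top} f)$.

Standardizing within the dimension being summed over keeps both
projections on a comparable z-score scale and, importantly, does not
saturate: a feature's score grows with the number of selected shared
elements in which it is over-expressed. (The transposed convention --
scoring features through $E^{(r)}$ -- caps a member feature's projection at
$\sqrt{H-1}$ noise standard deviations for $H$ shared elements, which at
desk-scale $H$ makes the conventional threshold range undiscriminating;
this is why the package adopts the convention above, the one used by the
iterative-signature family of algorithms.)

The threshold operator $\theta_t(x)$ keeps entries strictly greater than
$\mathrm{mean}(x) + t\,\mathrm{sd}(x)$ (population sd over the whole
vector), then divides the survivors by the largest surviving value, so
member scores lie in $(0, 1]$ and everything else is 0. Only
over-expression is sought: if the largest survivor is not positive the
support is treated as empty, since max-rescaling could not produce scores
in $(0,1]$.

One full cycle alternates: dataset-1 features from $s$; $s$ from dataset-1
features; dataset-2 features from $s$; $s$ from dataset-2 features.
Starting from a random seed set of shared elements, the cycle is repeated
until the three membership sets are identical in two consecutive cycles or
the largest absolute score change drops below `tol = 1e-3`, up to
`maxIter = 100` cycles; runs that empty a score vector or fail to converge
are discarded with a count. A converged run is a `CoModule`.

`runPPAGrid()` launches the iteration from every combination of seed and
threshold pair, with defaults matching the method's published operating
point: 10,000 random seeds (a uniform size, then a uniform subset of the
shared ids), feature thresholds 2.5-6 and shared thresholds 1-4.5. The
grids' step is 0.5; the same feature threshold is applied to both species.
Fixed points with identical membership triples are collapsed, keeping a
count of how many runs reached each (near-duplicates are left to
post-processing).

## Post-processing cascade

Three stages, each only removing co-modules, in this order:

1. **Redundancy elimination.** For a pair of co-modules, Pearson
   correlations $c_h$ and $c_m$ between their full-length per-species
   gene-score vectors (zeros for non-members) are multiplied; a product
   above 0.8 marks the pair redundant, and the co-module with the higher
   sum of its two feature thresholds is kept. The paper-level rule is
   pairwise; the global procedure here is greedy: candidates are visited
   in order of descending threshold sum (ties: larger total membership,
   then input order) and accepted unless redundant with an already-accepted
   co-module. Zero-variance score vectors make the correlation undefined;
   such pairs are treated as non-redundant, with a warning.
2. **Minimum size.** Co-modules with fewer than 10 features in either
   species are dropped.
3. **Fully-overlapping reduction.** Two co-modules "fully overlap" when
   one's species-1 gene set contains the other's. Within each connected
   component of this relation the co-module of maximal size -- size being
   the minimum of the two species' gene counts -- is kept (ties: larger
   species-1 set, then input order). Components rather than sequential
   pairwise merging make the result order-independent.

Note a consequence of stage 1 worth knowing when interpreting results: a
threshold sweep produces nested variants of the same underlying module,
and the rule deliberately keeps the *sharpest* variant of a redundant
chain. Recovered memberships are therefore conservative subsets of the
underlying module; validation of raw detection quality is done on the grid
output before the cascade.

## Expression conservation

Gene families are the connected components of the bipartite ortholog graph
(genes as vertices, ortholog pairs as edges); a one-to-one pair forms a
two-gene family. For a co-module with gene-level memberships $G_1, G_2$:

$$\gamma = \frac{n_{og}}{\min(\mathit{nfam}_h, \mathit{nfam}_m)}$$

where $n_{og}$ counts families represented in both $G_1$ and $G_2$, and
$\mathit{nfam}_h$ counts families represented in $G_1$ whose species-2
members appear on the species-2 array at all (not necessarily in the
co-module); $\mathit{nfam}_m$ symmetrically. When the denominator is 0,
$\gamma$ is undefined (`NA`) rather than 0 -- an empty side is no evidence
of non-conservation -- and such values are excluded from medians and tests.

Two reference distributions calibrate $\gamma$:

* **Permutation null.** The ortholog list is reshuffled so that the counts
  of one-to-one and many-to-many pairs are preserved exactly: species-2
  partners are permuted within the one-to-one pairs, and the distinct
  species-2 genes of the many-to-many pairs are relabeled by a random
  bijection (preserving every degree). Ten reshuffles are drawn per run
  and shared across co-modules; each co-module's null is the mean of its
  defined per-reshuffle gammas.
* **Replicate ceiling.** Running the same engine on two technical-replicate
  halves of one species (each organ's two replicates split at random)
  bounds the $\gamma$ achievable under the data's noise; there
  $n_{og}$ is the probe-set overlap of the two halves' memberships and the
  family counts are the membership sizes.

Real and null gamma lists are compared with a one-sided Mann-Whitney U
test (alternative: real greater). Exact enumeration is used when both
samples have fewer than 8 untied values; otherwise the normal
approximation with tie correction and no continuity correction, which
makes the no-shift case return exactly 0.5.

## Enrichment statistics

`hypergeometricOverlap()` gives the inclusive upper-tail hypergeometric
probability of a query/reference overlap in a finite universe;
`termEnrichment()` applies it per annotation term (one-sided Fisher on the
2x2 table is the identical test), flat across terms -- no ontology-graph
decorrelation is attempted. `bonferroni()` multiplies by the test count
and caps at 1; the dN/dS analysis uses 98 tests and a corrected
significance cutoff of 0.0005 by default. `dndsShiftTest()` compares a
co-module's dN/dS ratios against all genes' ratios (the co-module
included, as literally defined; a complement option exists) with a
two-sided rank-sum test: exact, tie-aware enumeration of the U
distribution when `choose(n, n_cm)` is at most 20,000 (two-sided by the
distance of U from its mean), normal approximation otherwise. Ratios are
defined only where $d_S > 0$.

## The synthetic testbed

`simulatePair()` generates what the analysis consumes: two replicate-level
matrices, a HOG map, an orthology with one-to-one and many-to-many
families, a probe-gene map and the planted truth. Defaults are the
validation study conditions: 12 HOGs x 2 replicates per species, 200
families (86.6% one-to-one, matching the published ortholog-pair ratio),
probes per gene distributed 80/15/5% over 1/2/3, three planted modules of
12 genes x 3 HOGs, over-expression effect 5 noise-sd, technical noise at
half the biological noise, conservation fraction $\rho = 0.8$.

Geometry was chosen once, for the following reasons. Modules must carry at
least 10 probe sets per species to pass the size filter, yet stay a small
fraction of the feature universe -- member-fraction inflation of the
threshold's standard deviation is what limits detectability (real atlases
have module fractions below 1%; 12 genes of ~200 is as small as the filter
permits). Shared-dimension scores saturate at $\sqrt{(H-k)/k}$ for a
module of $k$ of $H$ HOGs, so 3-HOG modules keep the 1-4.5 shared grid
meaningful at $H = 12$. Side-2 planted genes are the orthologs of a
$\rho$-fraction of the side-1 members plus fillers drawn from non-planted
one-to-one families, so the planted truth's $\gamma$ equals
$\mathrm{round}(\rho g)/g$ by construction.

What the generator does *not* emulate: microarray artifacts (probe GC
bias, saturation), non-Gaussian intensity distributions, correlated
baseline structure between organs, unbalanced replicate designs, and
modules that share genes or organs. Passing tests show the machinery is
correct and well-calibrated on clean planted structure, not that the
method's published organ-level findings follow.

`simulateReplicatePair()` emits two replicate halves of one species with
identical planted biology and independent technical noise.
`recoveryScore()` matches each planted module to the found co-module
maximizing the mean Jaccard across the organ dimension and both feature
dimensions.

## Numerical and design choices

* Population sd everywhere (normalization and thresholding): one stated
  convention makes the worked examples exactly reproducible.
* Convergence: membership stability over two consecutive cycles OR
  max score change < 1e-3; `maxIter = 100`; non-converged seeds dropped
  silently with a logged count.
* Strict inequality at the threshold cutoff, so constant vectors (sd 0)
  always empty.
* Constant rows/columns z-score to zero, with a warning.
* Fixed-point identity within a run is exact equality of the three
  membership sets.
* Ties everywhere are broken deterministically (documented per function),
  so a fixed RNG seed reproduces entire runs bitwise.
* The gene-matched pipeline mode restricts to one-to-one pairs, picks one
  probe set per gene at random (seeded) and applies only the redundancy
  stage of the cascade -- the minimum-probe-set filter is defined for
  probe-set features, and the gene-matched run's features are organs.
* HOGs present in only one species are excluded by the pipeline (both
  species must cover a shared element for it to be alignable).

## Validation problem sizes

The packaged tests validate against planted truth at 200 features x 12
HOGs with 200 seeds and the default grids (100 simulated data sets for the
recovery and null-separation checks; 100 each for the replicate-ceiling
ordering), conservation-fraction recovery at $\rho \in \{0.2, 0.5, 0.8\}$
(100 data sets each), and exhaustive enumeration of all small overlap
tables (universe up to 12). These sizes keep each check's Monte-Carlo
error well below the margins being asserted.

## Limitations

* Only over-expression is modelled; signed or down-regulated modules are
  not detected.
* Exactly two datasets; the engine does not generalize to three or more.
* The redundancy rule's preference for sharp variants biases
  post-processed memberships toward module cores (see above).
* $\gamma$ compares family *presence*, not expression levels; a family
  counted once can hide asymmetric paralog behavior.
* The permutation null preserves pair-class counts but not, e.g.,
  chromosomal neighborhoods or expression-level matching.
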
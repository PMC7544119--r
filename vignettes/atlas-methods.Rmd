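---
title: "Building cross-platform transcriptome atlases with rankatlas"
author: "rankatlas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building cross-platform transcriptome atlases with rankatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Public gene-expression compendia mix microarray intensities with RNA-seq
abundances. The two technologies differ structurally: microarrays report a
continuous signal with a non-zero background floor even for silent genes,
while RNA-seq reports discrete counts in which lowly expressed genes can be
exactly zero. A PCA of naively merged data clusters samples by measurement
platform, not by biology. `rankatlas` implements a deliberately simple
integration recipe for building a reusable PCA reference atlas from such
collections, and for projecting new bulk or pseudo-bulk single-cell samples
onto it without ever refitting:

1. **Rank percentile transform.** Within each sample, expression values are
   replaced by their rank percentile: the most expressed gene maps to 1,
   the least expressed to 0, values in between are uniformly spaced by
   rank, and ties receive the mean of their would-be ranks. Writing $r_g$
   for the 1-based average rank of gene $g$ among the $G$ genes of one
   sample, the percentile is $(r_g - 1)/(G - 1)$. The transform is
   monotone-invariant, so platform-specific dynamic-range distortions that
   preserve order vanish entirely; and it is per-sample, so new samples can
   be added without renormalising anything already transformed.
2. **Platform-variance gene filtering.** Ranking does not remove
   platform effects that reorder genes. For every gene the one-way
   fixed-effect model $y = X_p\beta_p + \varepsilon$ is fitted, with
   $X_p$ the platform membership of each sample, and the fraction
   $\sigma^2_p / (\sigma^2_p + \sigma^2_\varepsilon)$ of the gene's
   variance attributable to platform is computed
   ($\sigma^2_p = \mathrm{var}(X_p\hat\beta_p)$). Genes with a fraction
   at or above a threshold — 0.2 by default — are removed. Because both
   variances use the same (population) denominator the fraction is exactly
   the $R^2$ of the platform regression, which is how the package tests
   it against an independent ordinary-least-squares oracle.
3. **PCA atlas.** The retained genes are centred on their training means
   (no variance scaling, keeping the projection affine-linear in the
   percentiles) and a PCA is fitted. The model stores the gene list, the
   gene means, the orthonormal loadings, the explained variances and the
   training coordinates; the first three components are the display
   space. Each loading vector's sign is fixed so its largest-magnitude
   entry is positive, making coordinates reproducible across linear
   algebra backends.

Everything downstream — clustering, stability assessment, recursion,
projection — operates on this fixed model.

# Worked example

```{r example, eval = FALSE}
library(rankatlas)

sim <- simulateExpression(simConfig(seed = 1))
percentiles <- rankPercentile(sim$expression)
atlas <- fitAtlas(percentiles, buildConfig(threshold = 0.2))
atlas
labels <- clusterCoords(trainingCoords(atlas), k = 10, dims = 10, seed = 1)
proj <- projectSamples(atlas, sim$expression)
```

# Tunable parameters

* `threshold` (unitless fraction in (0, 1], default **0.2**): the
  platform-variance cutoff. Selection is strictly below the threshold, so
  boundary genes are excluded. Lower values remove platform structure more
  aggressively at the cost of discarding biology; the number of selected
  genes is non-decreasing in the threshold.
* `nComponents` (default **10**): retained principal components. Three are
  used for display and distance computations; ten support the per-component
  platform-dependence diagnostic.
* Clustering: k-means (25 restarts under a caller seed) or agglomerative
  clustering with Euclidean distance and Ward linkage (`hclust` method
  `ward.D2`, the Ward criterion on Euclidean distances). The cluster number
  `k` is chosen from a stability profile: the k immediately before the
  first strict decrease of the median H-index along the ascending k grid.
* Resampling: leave-one-dataset-out jackknife (one resample per
  contributing dataset) or bootstrap over samples (500 draws by default;
  dataset-level bootstrap is available via `unit = "dataset"`). Every
  resample re-runs the *complete* pipeline — variance partition, gene
  selection, PCA, clustering — so the reported stability covers the gene
  selection as well as the clustering.
* `poolSize` (default **9** cells): pseudo-bulk aggregation pools this many
  cells per draw, within a cluster, pools inheriting the cluster identity.
  Eight to ten cells per pool approximates bulk data structure for
  10x-style counts; equal pool sizes keep pools exchangeable, and remainder
  cells are dropped by default.

# Stability: the Jaccard H-index

For one original cluster, each resample contributes the maximum Jaccard
similarity between that cluster and any cluster of the re-run pipeline
(computed over the samples the two clusterings share; bootstrap duplicates
are collapsed to unique ids first). A profile $J_1, \dots, J_B$ over $B$
resamples is summarised by its continuous H-index: the largest
$h \in [0,1]$ such that at least a fraction $h$ of the resamples achieved
$J_b \ge h$. The index is 1 exactly when the cluster is recovered
perfectly in every resample, and is invariant to cluster relabelling and
resample order. Matching is per-original-cluster by maximum Jaccard (in
the style of bootstrap cluster-wise stability assessment), not an optimal
one-to-one assignment: simpler, monotone, and standard.

# Variance diagnostics

Two per-gene decompositions are provided. The **ANOVA fraction** above
drives gene selection and is computed in closed form from platform group
means. The **LMM diagnostic** contrasts biology with platform directly:
percentiles are mapped into the open unit interval with the continuity
correction $p' = (p(G-1) + 0.5)/G$, probit-transformed, and a
two-random-intercept model
$y = \mu + Z_{\mathrm{class}}\alpha_{\mathrm{class}} +
Z_{\mathrm{platform}}\alpha_{\mathrm{platform}} + \varepsilon$ is fitted by
REML (`lme4::lmer`). Genes are orderable by the class/platform variance
ratio. Per-component platform dependence of a fitted atlas is measured by
the Kruskal–Wallis H statistic of each component's training coordinates
grouped by platform.

# What the simulator emulates — and what it does not

`simulateExpression()` generates the package's test bed: by default 2,000
genes, 10 cell types, four platforms (two microarray-like, two
RNA-seq-like), two datasets per platform and five samples per dataset and
cell type — 400 samples. Baseline log2 abundance is Normal(6, 2); marker
genes (2.5% of genes per cell type, disjoint across types) are shifted up
by 3 log2 units in their type; half the genes are platform-affected,
receiving per-platform additive shifts and multiplicative slopes on the
log2 scale; small per-(gene, dataset) offsets model residual batch
structure; i.i.d. Normal noise (sd 1 log2 unit) is added per measurement.
Microarray platforms emit `2^signal` plus a background floor of 32
(continuous, strictly positive); RNA-seq platforms emit negative-binomial
counts (size 10) with 5% extra dropout zeros. These defaults are the
package's chosen study conditions: marker effects of ~8-fold with
within-type noise of ~2-fold, and platform distortions of the same order
as the biology, are typical of what curated public compendia show after
probe-level processing.

The per-gene distortion scale is drawn from an exponential distribution
(`distortionProfile = "heterogeneous"`), because in real data platform
effects vary continuously across genes — most probes drift mildly, a few
fail outright — producing the continuous spread of platform-variance
fractions that motivates a threshold in the first place. A `"uniform"`
profile, in which every affected gene receives the same distortion scale,
is available for experiments that need a clean affected/unaffected
dichotomy (for example, measuring how strongly affected genes are depleted
by selection).

The simulator does *not* model gene–gene correlation beyond the shared
marker blocks, gene length or GC biases, doublets, or library-size
variation. Tests passing on simulated data therefore demonstrate that the
pipeline removes platform structure it is designed to remove and recovers
cell-type structure of realistic magnitude — not that any particular real
compendium will yield a given number of selected genes.

# Numerical and design choices

* **Percentile formula.** Forced endpoints at 0 and 1 with uniform spacing
  give $(r-1)/(G-1)$; a fully tied sample maps to 0.5 everywhere (the
  average rank $(G+1)/2$ lands there exactly). RNA-seq zeros tie together
  and share one low percentile; no special zero handling exists.
* **Projection.** A new sample is ranked over its own full measured gene
  set and then restricted to the atlas genes; atlas genes missing from the
  sample receive percentile 0 (the lowest rank). A warning is emitted when
  more than half the atlas genes are missing. Ranking before restricting
  (rather than over atlas genes only) keeps a sample's percentiles
  independent of which atlas is targeted.
* **Off-atlas caution flag.** The score is the Euclidean distance, in the
  three display components, to the nearest training sample; the flag
  trips above the 95th percentile of the training samples' own
  nearest-neighbour distances. This is a pragmatic formalisation of
  "lands far from every populated region"; the quantile is configurable
  and the score is always reported alongside the flag.
* **Recursion.** A sub-atlas re-runs variance partitioning, selection and
  PCA from scratch on the sample subset. Subset-specific selection is the
  point: genes discarded globally for platform dependence may be clean and
  informative within one lineage, and vice versa.
* **Degenerate inputs.** Constant genes get fraction 0 (0/0 := 0) in the
  ANOVA and a non-convergence flag (components `NA`) in the LMM; platforms
  with a single sample inflate their own fitted mean and trigger a
  warning; `k` equal to the number of samples returns singleton clusters
  without invoking k-means.
* **LMM recovery testing.** The recovery tests simulate directly from the
  two-random-intercept generative model on the probit scale with variance
  components in ratio 4:1:1 scaled to unit total variance, then map
  through the normal CDF to obtain percentile-scale values. The scaling
  matters: the checked quantities are the variance *proportions*, which
  are scale-invariant, while an unscaled simulation would saturate the
  unit interval and be censored by the continuity correction.
* **Platform-dependence sweep.** Platform group means span a space of rank
  one less than the number of platforms, so with four platforms at most
  three components can carry pure platform signal and the median over ten
  components is uninformative. The sweep diagnostic (and its test) runs on
  an eight-platform panel, closer to the platform diversity of real
  multi-generation compendia, where tightening the threshold from 0.8 to
  0.2 visibly drives the median Kruskal–Wallis H down.

# Problem sizes used in the test suite

The shipped tests and the acceptance script run entirely on simulated
data: the default 2,000-gene, 400-sample compendium for end-to-end
recovery; 50-resample bootstraps for stability; 1,000 random small
instances for the ANOVA oracle; 50 genes at 200 samples for LMM recovery.
These sizes are chosen so the complete validation remains comfortable on a
single CPU while keeping Monte-Carlo error well inside the asserted
margins.

# Known limitations

Rank transformation discards the magnitude of expression differences, and
gene filtering removes some genuinely informative genes along with
platform-sensitive ones — both are accepted costs of robust integration.
Samples whose biology is orthogonal to the atlas project toward the centre
of the space rather than to a "correct" position; the off-atlas flag
mitigates but cannot eliminate misreading such projections. Individual
single cells should not be projected directly — their value distribution
is too far from bulk — which is why the pseudo-bulk aggregator exists.
Dataset-level batch effects within a platform are deliberately not
modelled in the selection step; they are assumed to average out across the
multiple datasets covering each biology, and the jackknife
(leave-one-dataset-out) stability check is the guard on that assumption.
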
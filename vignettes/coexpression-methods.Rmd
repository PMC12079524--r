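---
title: "Weighted co-expression modules and driver-anchored prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted co-expression modules and driver-anchored prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

# The analysis in one paragraph

`coexmod` takes a log2 expression matrix (genes x samples), keeps the most
variable genes, builds a weighted gene co-expression network with robust
(biweight mid-) correlation raised to a soft-threshold power, clusters the
topological-overlap dissimilarity into modules with an adaptive tree cut,
summarizes each module by its eigengene, and then asks three questions about
the modules: are they robust to the clustering hyperparameters; do they
replicate in other datasets and conditions (permutation preservation and
differential co-expression); and which module genes are the best candidates
around a *driver* gene of interest — a gene whose expression anchors the
biology, such as a regulator of foamy-macrophage formation in
atherosclerotic plaque, where one looks for hub genes strongly
anti-correlated with the driver and differentially expressed between plaque
and normal artery. A synthetic-data generator with planted modules, a
planted driver and a planted candidate makes every one of these stages
testable without any external download.

# Network construction

**Robust correlation.** Pairwise gene similarity is the biweight
midcorrelation: observations are weighted by Tukey biweights
`w = (1 - u^2)^2` with `u = (x - med(x)) / (9 mad(x))`, where `mad` is the
raw median absolute deviation (no 1.4826 consistency constant — the
canonical definition of the estimator uses the unscaled MAD). A vector with
zero MAD cannot be weighted and falls back to mean centering, i.e. Pearson
behaviour, for that vector. Microarray expression values carry occasional
gross outliers; a single 6-SD cell among 40 samples moves a Pearson
correlation by more than 0.1 but a biweight midcorrelation by less than
0.05 (this is asserted by the test suite using the generator's outlier
plan, 1% of cells at 6 SD).

**Soft threshold.** Unsigned adjacency is `|r|^beta` (signed
`((1+r)/2)^beta` is available via `network_config()`). The default
`beta = 8` is retained when the scale-free fit of the connectivity
distribution reaches `R^2 > 0.8`; `pick_soft_threshold()` reports the fit
table over candidate powers and selects the smallest power reaching the
target. The fit bins connectivities into 10 equal-width bins and regresses
log-frequency on log-connectivity; a non-negative slope flags the fit
invalid, since a scale-free degree distribution must decay. The unsigned
default follows from the analysis goal: the driver-anchored screen looks
for *negatively* correlated genes, which an unsigned network keeps inside
the same module.

**Topological overlap.** `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 -
a_ij)` with `l_ij` the shared-neighbour sum; `1 - TOM` is the clustering
dissimilarity. Isolated pairs (zero denominator) get TOM 0 by convention.

# Module detection

Average-linkage hierarchical clustering of `1 - TOM` is cut with a
two-stage adaptive procedure (`cut_dynamic_hybrid()`):

1. **Static cut + decomposition.** The tree is cut at
   `hmin + cut_height (hmax - hmin)` (default 0.99 of the height range).
   Each branch below the cut is decomposed by walking down its trunk:
   side-branches smaller than `min_module_size` are peeled, and the branch
   splits at the first merge whose two sides both look like module cores.
   A side qualifies when the mean height of its core merges (the lowest
   `m + sqrt(size - m)` merges) is low relative to the local span
   (core scatter) and the splitting height clears the core top by a
   sufficient fraction of the local span (gap). `deep_split` (0-4) maps to
   five (core-scatter, gap) constant pairs — 0.64/0.27 up to 0.95/0.0375,
   following the dynamic-tree-cut convention — so larger values split more
   aggressively. Accepted branches are then *trimmed*: a leaf stays only if
   its average dissimilarity to the branch core is within three quarters of
   the distance between the core's own median and the background median.
   This matters because background genes accrete onto strong branches just
   below the static cut; distance-to-core separates them from genuine
   members far more reliably than attachment height.
2. **PAM stage.** Each unassigned gene may join the module with the
   smallest average dissimilarity to its members, provided that average is
   (i) below the gene's average dissimilarity to non-members, (ii) below
   the static cut height, and (iii) no larger than the average intramodule
   dissimilarity of the module's loosest member. Guard (iii) is essential
   on powered-TOM dissimilarities: thousands of background genes satisfy
   (i) by vanishing margins, and without (iii) they would flood the
   modules.

Modules whose eigengenes correlate above `1 - merge_threshold` are merged
(closest pair first, eigengenes recomputed after every merge), labels are
assigned by descending size, and the color naming follows the familiar
turquoise/blue/brown convention with grey reserved for unassigned genes.
The grey pseudo-module is excluded from every downstream stage.

**Known limitation.** The split criteria judge a branch by its core, which
makes them robust to stragglers but means a tight branch with *no* internal
structure whose merge heights carry metric jitter can occasionally be
subdivided; conversely a structureless loose branch below the cut is
rejected by the trimming step rather than by an explicit scatter test.
These trade-offs are deliberate: on the factor-model data the package is
designed around, planted modules are recovered with adjusted Rand index
above 0.9 at every point of the default hyperparameter grid.

**Hyperparameter robustness.** `hyperparameter_sweep()` re-runs cut + merge
over a grid (default: deep split 1-3, minimum size 20/30, merge threshold
0.15/0.25, PAM on/off — 24 points) and reports module counts and the
pairwise adjusted Rand index between partitions, with unassigned genes as
their own class. A median pairwise ARI near 1 is the quantitative meaning
of "the modules are robust to the hyperparameters".

# Eigengenes, hubs and module-trait correlation

The module eigengene is the first right singular vector of the
standardized member expression, scaled to unit variance across samples and
oriented so its mean correlation with members is non-negative; the first
squared singular value over the total gives the variance explained.
Per-gene statistics are `kME` (correlation with the own-module eigengene)
and `kIM` (intramodular connectivity, the sum of within-module adjacency);
hub ranks order by `kIM` with `kME` as tie-break, because "connectivity"
in the network sense is adjacency-based, while `kME` remains available as
an alternative ranking. Module-trait relations are Pearson correlations of
eigengenes with numeric traits over a stated sample subset (by default the
case-condition samples, matching the practice of correlating against
driver expression within the diseased tissue).

# Preservation and differential co-expression

**Cross-dataset preservation** (`permutation_preservation()`) computes
seven statistics per module on the gene overlap of two datasets: four
density statistics in the test data (mean intramodule correlation, mean
adjacency, eigengene variance explained, mean |kME|) and three
pattern-agreement statistics between datasets (rank correlations of kIM,
of kME, and of the vectorized intramodule correlations). The null draws
random gene sets of equal size from the analyzed universe, one draw per
permutation shared across statistics; `p = (1 + #{null >= obs}) /
(n_perm + 1)` so the smallest attainable p is `1/(n_perm+1)`. A module is
*significantly preserved* when all seven p-values fall below 0.05, and
`Zsummary` is the median of the density-median and connectivity-median Z
scores. The pattern statistics use Spearman correlation deliberately: a
random draw containing even two co-members of a strong module produces a
two-point-leverage pattern whose Pearson correlation is near 1, which
would make the null stochastically *larger* than a genuine module's
statistic; rank correlation removes the leverage so the null honestly
encodes "no reproducible pattern". The identity of the seven statistics is
a reconstruction of the standard module-preservation toolbox; the set is
exposed as plain columns so a different selection can be scored without
code change.

**Differential co-expression** (`diff_coexpression()`) compares intramodule
correlation structure between two conditions with
`D = mean |cor_A - cor_B|` over member pairs and per-gene analogues, and
permutes condition labels — within pairs for paired designs — for
significance. A module is "preserved across conditions" when its
permutation p exceeds 0.05. Both a cross-dataset test and a cross-condition
test are provided because a module can replicate in an independent cohort
while still rewiring between disease and control tissue.

# Signature scoring and candidate prioritization

**Rank-based signature scores** (`signature_score()`): per sample, all `G`
genes are ranked, ranks are normalized to `[0, 1]`, and the score is the
mean normalized rank of the `S` signature genes, min-max standardized by
its attainable extremes so that occupying the top `S` ranks scores exactly
1. Because the score depends on the data only through within-sample ranks,
it is *exactly* invariant under any strictly increasing per-sample
transform — the operative meaning of "robust to differences between
samples and datasets", and the reason scores can be compared across
platforms without normalization gymnastics. The scoring function is the
package's reconstruction of an under-specified ranking scheme; it is
deliberately the simplest construction with that invariance.

**Validation** (`validate_signature()`): each module's top-`k` hub genes
(default 120) form a signature; the module whose hub score best correlates
with a reference signature score across an independent cohort is the one
whose program tracks the reference biology.

**Candidate ranking** (`rank_candidates()`): module genes are screened by
the sign of their Pearson correlation with the driver and a raw `p < 0.05`
threshold (BH-adjusted q-values are reported alongside; the raw-p screen
mirrors the conventional reporting of driver-anticorrelation counts), and
eligible genes are ordered by the unweighted mean of their fractional hub
rank and fractional correlation-strength rank. The equal weighting is a
declared reconstruction — the weights are arguments, not constants. The
top-`N` (default 47) eligible genes are flagged and handed to the paired
t-test for differential-expression confirmation, and optionally to the
hypergeometric over-representation test against user-supplied gene sets.

# The synthetic-data generator

`simulate_dataset()` draws from an explicit Gaussian factor model so every
planted quantity has a closed-form population target:

* Eigengenes `e_q` and member genes `x_i = sqrt(rho_i) e_q +
  sqrt(1 - rho_i) eps_i`; member signal shares are evenly spaced over
  `rho_q +/- rho_spread` (defaults: module means from 0.725 down to 0.575,
  spread 0.075, i.e. all member-member correlations inside [0.5, 0.8]),
  giving each module the hub-to-periphery gradient without which hub
  ranking would be meaningless.
* A planted driver with target eigengene correlations `c_q` (defaults
  +0.90, -0.70, +0.66 for modules 1-3). Because `sum(c^2) > 1`, these
  targets are unrealizable with mutually independent eigengenes; the
  default `coupled` structure therefore gives the eigengenes the *smallest*
  mutual correlations `cor(e_q, e_r) = t c_q c_r` (minimal `t >= 0` for
  positive semi-definiteness) that accommodate the plan. Strongly
  driver-correlated modules are necessarily inter-correlated — a fact of
  the covariance geometry, not a modelling convenience — and the minimal-`t`
  choice keeps them as separable as the plan permits. When
  `sum(c^2) <= 1` the construction reduces to exactly independent
  eigengenes, which is also available explicitly (with a hard error on
  unrealizable plans) via `eigengene_structure = "independent"`.
* A planted candidate hub in the anti-correlated module with its own
  planted driver correlation (default -0.75, hub strength 0.9) and an
  additive case-condition shift (default 0.5 log2 units), emulating an
  upregulated hub candidate. The joint realizability of hub strength and
  driver correlation is checked before sampling.
* A paired two-condition design (default 40 samples in 20 pairs) whose
  per-gene pair effects are folded *inside* the unit residual variance, so
  the population gene-eigengene correlations remain exactly `sqrt(rho_i)`.
* An outlier plan (fraction of cells replaced by `mean +/- magnitude * SD`
  values; documented plan 1% at 6 SD, off by default) for robustness
  studies, and `make_validation_cohort()` for independent cohorts sharing
  the module structure, optionally with per-gene location/scale or
  per-sample monotone distortions.

What the generator does *not* emulate: batch structure, probe saturation,
count noise, correlated background genes, or any annotation-level
artefact. Passing tests therefore demonstrate that the algorithms recover
the structure they were designed for at realistic sample sizes — not that
any particular real dataset satisfies the factor model.

# Numerical choices and problem sizes

Permutation p-values use the add-one correction and are exactly
reproducible from the seed; every stochastic function takes an explicit
seed and restores the caller's RNG state. Default permutation count is 200
(about +/-0.03 of standard error at p = 0.05); the test suite uses 50-200
depending on the property under test. The packaged analyses run at the
scaled-down study size the generator encodes — 2000 genes, 40 samples —
and the heavier statistical-calibration checks use 60-150 samples with
100-1000 genes; these sizes were chosen so that every planted effect is
comfortably detectable by design rather than by luck. Ties are broken
deterministically throughout (lexicographic gene IDs; average ranks within
samples), so identical inputs give byte-identical outputs.
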
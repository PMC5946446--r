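---
title: "Detecting oocyte-cumulus regulatory crosstalk: models and design choices"
author: "cocnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting oocyte-cumulus regulatory crosstalk: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocnet)
```

# The analysis problem

A cumulus-oocyte complex (COC) is sampled three ways: the oocyte, the
inner cumulus layer adjacent to the zona pellucida (innerCC), and the
outer cumulus layer (outerCC). With J complexes profiled, each gene has
a J-vector of expression per compartment, and the question is whether
genes in one compartment co-vary with genes in another *across
complexes* — the transcriptional signature of regulatory communication
— and how that co-variation is organized: into co-expression modules,
into ligand-receptor channels, into compartment-specific variability.

`cocnet` is organized around a `COCExperiment` (a
`SummarizedExperiment` whose columns carry a COC identifier and a
compartment label), and the analysis proceeds in stages that can be
run individually or end-to-end with `runCocPipeline()`.

# Expression presence

A gene counts as expressed in a compartment when its FPKM exceeds 0.5
in at least 8 of that compartment's samples (`filterExpressed()`,
defaults `minFpkm = 0.5`, `minSamples = 8`). Both bounds are
parameters; the threshold is strict, so a value of exactly 0.5 never
counts. Filtering is *per compartment*: a gene can be expressed in the
oocyte and absent from the cumulus, and it is exactly this asymmetry
that later drives the autocrine/paracrine classification. Missing
values are not supported — absence must be encoded as 0, which is how
FPKM tables behave. All correlation work happens on log2(FPKM+1)
(`logTransform()`).

# Robust cross-compartment correlation

`bicor()` implements the biweight midcorrelation. For a vector x with
median m and unscaled median absolute deviation MAD(x):

$$u_i = \frac{x_i - m}{9\,\mathrm{MAD}(x)},\qquad
  a_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1],\qquad
  \tilde x_i = \frac{(x_i-m)\,a_i}{\sqrt{\sum_j ((x_j-m)\,a_j)^2}}$$

and $\mathrm{bicor}(x,y)=\sum_i \tilde x_i \tilde y_i$. Observations
beyond 9 MAD get zero weight; with 16 complexes a single outlying COC
cannot dominate a gene pair. No outlier-probability cap is applied —
the classic form only.

**Degenerate vectors.** When MAD(x) = 0 (at least half the samples
share the median value) the biweight is undefined. The default follows
the behavior documented for the reference implementation of this
estimator: that *vector* falls back to the Pearson standardization and
every pair touching it is flagged (`fallbackA`/`fallbackB` on the
`BicorResult`). In `fallback = "strict"` mode such genes yield NA and
are excluded from counts. A fully constant vector is NA in either
mode.

`crossCompartmentBicor()` computes all |A-genes| × |B-genes| pairs via
a single cross-product of the per-gene transformed rows; no
within-compartment pairs are formed at this stage.

# Permutation empirical FDR

The null model breaks the COC linkage: `permutedNullBicor()` applies a
uniformly random non-identity permutation to the COC index of the
compartment-A matrix and recomputes all K pairwise correlations, B
times. Because the biweight transform of a gene does not depend on
column order, the transform is computed once and only the
cross-product is repeated, which is what makes B = 1000–10,000
affordable. When $J! - 1 \le B$ the sampler switches to exhaustive
enumeration of all non-identity permutations (e.g. all 23 at J = 4).
Duplicate permutations are allowed in the sampled regime — at J = 16
the collision probability over 10,000 draws is negligible.

For each threshold t on a declared grid (default 0.50–0.95 in steps of
0.05),

$$\mathrm{eFDR}(t)=\sum_{b=1}^{B}
  \frac{\#\{\text{pairs}: |\mathrm{bicor}^{0b}| \ge t\} + 1}{KB+1},$$

capped at 1. Two tie conventions are deliberate and tested: the *null*
comparison is $\ge t$ (counting every permuted value at least as
extreme), while *pair selection* is strict, |bicor| > t. The estimator
has a floor of $B/(KB+1)$ (the +1 terms alone), so the smallest
reportable eFDR is roughly 1/K — at desk scale (K ≈ 10⁴, B = 10³) about
10⁻⁴. `selectSignificantPairs()` keeps pairs with |bicor| > 0.85 only
when the eFDR at that grid value clears `efdrMax` (default 0.001); the
threshold must be on the grid — there is no interpolation. The two
compartment pairings (oocyte–innerCC, oocyte–outerCC) are processed
independently with independent child seeds.

# Co-expression structure

**Within a compartment.** `signedAdjacency()` maps correlation to
$a_{ij} = ((1+\mathrm{bicor})/2)^\beta$, so anti-correlated genes are
*disconnected* (signed network) and weak correlations are suppressed by
the soft power. β is not identifiable from first principles; the
default 12 is the convention for signed networks and every module
result should state its β. `tomSimilarity()` then measures shared
neighborhood:

$$\mathrm{TOM}_{ij}=\frac{\ell_{ij}+a_{ij}}{\min(k_i,k_j)+1-a_{ij}},
 \qquad \ell_{ij}=\sum_{u\ne i,j} a_{iu}a_{uj},$$

and `hierarchicalModules()` clusters 1−TOM by average linkage with
static tree cuts; clusters below `minSize` become unassigned (label
0), and labels are renumbered by decreasing size with lexicographic
tie-breaks so they are invariant to input gene order. Because "average
linkage with Euclidean distance on a matrix that is already a
dissimilarity" is a known ambiguity, the default treats 1−TOM directly
as the dissimilarity (the standard idiom for this network family);
`method = "euclidean"` instead clusters the Euclidean distances
between dissimilarity rows. Both paths are tested. Dynamic tree
cutting and module eigengenes are out of scope.

**Across compartments.** The significant-pair bicor matrix is
rectangular, so no direct gene×gene dissimilarity exists per
dimension; `crossCompartmentClusters()` therefore clusters rows (and,
independently, columns) of 1−bicor by the Euclidean distance between
them — the two-dimensional reading of the same average-linkage recipe.
The sign structure is preserved (1−bicor, not 1−|bicor|), and each (A
cluster, B cluster) block is summarized by its mean bicor, the
statistic that exposes coherently positive or negative cross-compartment
blocks. Default cut heights are 70% of each tree's height and are
*illustrative*: the interesting structure, not one canonical
partition, is the object here, and callers should pass explicit
heights when comparing runs.

# Variable genes

For genes detected in **all** samples of a compartment (FPKM > 0 in
every sample — a deliberately weaker rule than the presence filter,
and configurable), `perGeneCv()` computes the per-gene SD x of
log2(FPKM+1) with the n−1 denominator and

$$CV=\sqrt{e^{x^2}-1}.$$

This is the log-normal CV identity, which strictly presumes a
natural-log SD; the convention here plugs the log2-scale x in
directly, and `naturalLog = TRUE` rescales x by ln 2 first for users
who want the literal identity. `topVariableGenes()` uses the
nearest-rank percentile and strict exceedance, and reports the CV
cutoff so selections at, say, the 90th or 95th percentile can be
compared across datasets.

# Ligand-receptor road map

`integratePpi()` merges edge lists from multiple interaction databases
into one unordered, deduplicated gene-level edge set, expanding foreign
ids through a homology map (one edge per mapped combination, one-to-many
allowed), unioning provenance, and dropping (with counts) unmapped
endpoints and self-edges. `designateRoles()` marks receptors by exact
GO term ("receptor activity", "receptor complex") with no ontology
propagation — these are already the broadest receptor terms — and
emits ligand→receptor candidates; receptor-receptor edges yield both
orientations, flagged, and are excluded from classification counts by
default.

`classifySignaling()` is a pure function of presence categories. With
cumulus presence pooled over the two layers (the default; a per-layer
reading is available by passing `innerCC`/`outerCC` sets), each gene is
oocyte-only, CC-only or both, and the 3×3 table resolves to 2
autocrine, 2 paracrine (with direction) and 5 autocrine-or-paracrine
cells; pairs whose ligand or receptor is expressed nowhere are
dropped.

`fitScaleFree()` regresses log10 degree-frequency on log10 degree (raw
frequencies, no binning) and reports R². The bootstrap null for its
p-value is not canonical; the choice here is Erdős–Rényi graphs with
the same node and edge counts, giving
$p = (\#\{R^2_{null} \ge R^2\}+1)/(n_{boot}+1)$, which is exact-valid
and has floor $1/(n_{boot}+1)$. `hubSummary()` reports the fraction of
edges incident to the top-n degree genes (ties lexicographic).

# Length-aware enrichment

Long genes are over-detected in expression-derived gene lists, which
inflates naive hypergeometric enrichment. `fitPwf()` estimates the
selection-vs-length trend by isotonic regression of per-bin selection
proportions on bin mean length (40 equal-count bins by default,
reduced for small universes; degenerate inputs fall back to constant
weights with a warning), floored at a small positive value and
rescaled to mean 1. `walleniusTest()` converts the weights to one odds
ratio per category — mean weight inside over mean weight outside — and
computes the upper tail under the Wallenius noncentral hypergeometric
distribution with an **exact** forward recursion over draws for the
two-weight-class urn (O(n·m) and numerically stable in probability
space), rather than an asymptotic approximation; at odds 1 it
reproduces the central hypergeometric tail to numerical precision.
Only over-representation is tested. `enrichAll()` applies this per
gene set (e.g. per module) against the compartment's expressed genes
as the universe and always emits both BH and BY FDR columns, since
either multiple-testing convention may be wanted and the BY variant is
valid under dependency. Significance thresholds (0.2, 0.1, 0.05) are
the caller's, never hard-coded.

# The synthetic-data generator

`simulateCocDataset()` draws, per compartment, latent standard normals
over the COC index and injects structure there: a planted
cross-compartment pair sets $z_b = \rho z_a + \sqrt{1-\rho^2}\epsilon$;
a planted module shares a common factor at correlation r. Observed
values are $\log_2(\mathrm{FPKM}+1) = \mu_g + \sigma_g z$ (floored at
0) and FPKM $= 2^v - 1$ — a Gaussian copula, so planted correlations
survive the monotone transform with only mild distortion (the rank
correlation of a planted pair converges to $(6/\pi)\arcsin(\rho/2)$),
while FPKM stays non-negative, which a direct multivariate normal on
FPKM would violate. Genes absent in a compartment are exactly 0 there.

Defaults encode the study conditions this generator emulates: 16 COCs;
per-compartment presence probabilities (0.52, 0.31, 0.53) mirroring
detection fractions typical of single-COC transcriptomes, with the
inner cumulus sparsest; per-gene means uniform on 2–6 log2 units and
SDs uniform on 0.4–1.0, which puts median CVs in the 0.7–0.8 range
observed for genes detected in all samples. One global seed expands
into per-stage child seeds by a fixed affine scheme (`seed*7919 +
stage*104729 mod 2^31−1`), so stages are independently reproducible
and a rerun is bit-identical.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data: batch structure, sequencing
noise and read-level artifacts, heavy-tailed or zero-inflated
expression beyond the presence mechanism, dependence between a gene's
presence pattern and its expression level, and correlated PPI/GO
annotation errors. `simulatePpiNetwork()` grows a
preferential-attachment graph (approximately scale-free by
construction) with a receptor fraction; `simulateGoUniverse()` selects
an "interesting" set with a log-odds bump for planted-term members and
a length-bias slope — the artifact the PWF correction removes.

# Numerical choices and degenerate inputs

* Correlations are clamped to [−1, 1] after the cross-product to
  absorb rounding.
* eFDR grids are matched with tolerance 1e-9; off-grid selection
  thresholds are an error.
* Tree-cut heights below 0 warn and return an all-unassigned result;
  any height ≥ 0 is valid (a height above the root yields one
  cluster).
* Wallenius recursion runs in probability space (mass vectors sum to
  1) with impossible states carrying zero mass; categories spanning
  the whole universe get p = 1 with a flag.
* `fitScaleFree()` requires ≥ 10 connected nodes and ≥ 2 distinct
  degrees ("degenerate degree distribution" otherwise); a two-point
  fit legitimately reports R² = 1.
* Pipeline outputs are written with deterministic row order and a
  manifest of md5 checksums; rerunning a config with the same seed
  reproduces every file byte-for-byte.

# Problem sizes used in the validation suite

The test suite and `scripts/acceptance.R` run at desk scale, chosen to
exercise every code path with tight oracles: 1000 random vector pairs
for the bicor transcription oracle; exhaustive permutation enumeration
at J = 4 (23 permutations) for the eFDR; 16 COCs, 50 planted pairs at
|ρ| = 0.98 among ~10,000 null pairs with B = 1000 for planted
recovery; 100 random 6-node matrices for the TOM triple-sum oracle;
urns of population ≤ 20 for Wallenius enumeration plus 500 randomized
null p-values for distributional calibration; 500-node
preferential-attachment and Erdős–Rényi graphs (100 seeds) for the
scale-free calibration; and a 60-gene three-compartment pipeline run
(twice) for end-to-end determinism.

# Known limitations

* The eFDR floor scales as 1/K·(B/(B+1/K)) ≈ 1/K: very small eFDR
  gates (e.g. 10⁻⁵) require commensurately large B and K.
* Per-pair permutation p-values are not computed — only the grid eFDR,
  matching the framework's design; within-compartment pairs get no
  permutation FDR at all.
* The scale-free p-value depends on the chosen Erdős–Rényi null; other
  nulls (degree-preserving rewiring) answer a different question.
* GO term relationships are ignored (no propagation, no redundancy
  reduction); enrichment rows are per-term, marginally.
* Cross-compartment cluster labels depend on cut heights; defaults are
  starting points for exploration, not canonical partitions.
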
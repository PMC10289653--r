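---
title: "Methods: models, parameters, and design choices in wbatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in wbatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

wbatlas turns a labeled single-cell count matrix — the kind produced by a
whole-body atlas experiment on a small metazoan such as adult *C. elegans* —
into five derived analyses: per-cell-type expression profiles with bootstrap
confidence, transcriptome-coverage estimates, housekeeping-gene scores,
TF-activity maps from ChIP-seq binding, and ligand-receptor (LR) cell-cell
communication signatures. This vignette documents the models behind each
stage, the tunable parameters, the synthetic-data generator used to validate
everything, and the design choices made where the method left room.

## Cell-type profiles (aggregation)

Counts are first normalized per cell by the size factor
$s_j = \mathrm{total}_j / \mathrm{geomean}(\mathrm{totals})$, the documented
default of the single-cell pipelines this workflow sits downstream of; it is
scale-equivalent to library-size normalization and leaves the geometric mean
of totals unchanged. The profile of a cell type is then built in five steps:
subset the normalized matrix to the type's cells, take each gene's mean,
divide by the sum of those means, and multiply by $10^6$. The result, *scaled
TPM*, is compositional: each cell-type column sums to one million by
construction.

Uncertainty comes from a within-cell-type bootstrap: for a type with $N$
cells, $N$ cells are resampled with replacement and the whole profile is
recomputed; the default `n_boot = 1000` resamples give percentile intervals
at the 95% and 80% levels. Percentile (rather than BCa) intervals are used
because only the interval endpoints are consumed downstream and the
percentile form is exactly reproducible from the resample quantiles. A gene
is *robustly expressed* in a type when the 95% lower bound is strictly
positive. The bootstrap is implemented as a resample-weight matrix
multiplication, so a profile over 2,000 genes and 150 cells takes well under
a second per cell type; every (cell type) resampling stream is seeded
separately, making results bit-reproducible.

"Percent expressed" is computed from detection — a raw count above zero —
not from normalized values, since detection is what the statistic describes.

## Transcriptome coverage

For each cell type, `downsample_curve()` samples $s$ cells without
replacement (100 iterations per size by default) and counts genes detected in
the subsample. Because scaled TPM is a positive rescaling of per-gene means,
"scaled TPM > 0" is equivalent to "any count > 0 in the subsample", and the
implementation counts the latter; a unit test asserts the equivalence at full
size. The default size grid is 10 sizes geometrically spaced from 5 to $N$.

The mean curve is fitted with the three-parameter log-logistic function
$$ f(x) = \frac{d}{1 + \exp\!\big(b(\log x - \log e)\big)} $$
parameterized so that $d$ is directly the predicted maximum gene count
(G\_MAX, in genes), $e$ the number of cells at which half of G\_MAX is
detected (cells), and $b < 0$ the slope. $f(e) = d/2$ holds exactly. Fitting
uses Levenberg–Marquardt (`minpack.lm::nlsLM`) from a grid of 18 starting
points (three slopes, three size quartiles for $e$, two inflations of the
curve maximum for $d$), keeping the best residual sum of squares; lower
bounds keep $d, e > 0$. The reported coverage of the observed $N$ cells is
$f(N)/d$, clamped to $[0, 1]$.

## Housekeeping scores

Two statistics are computed per gene across cell types:

* **Skewness score** — the population moment skewness
  $g_1 = m_3 / m_2^{3/2}$ of the per-cell-type percent-expressed vector.
  The method description names a skewness "function" without a formula; $g_1$
  is the common default, only the sign and ordering are used downstream, and
  an alternative estimator remains available through the `type` argument
  (default unchanged). Genes expressed in most cells of most types score
  negative.
* **Gini coefficient** — $G = \sum_{ij} |x_i - x_j| / (2 n^2 \bar x)$ over
  the scaled-TPM vector, computed via the equivalent sorted form and verified
  against the pairwise sum in the tests. 0 is perfectly even expression;
  a one-hot vector gives $(n-1)/n$.

Genes with zero expression everywhere have both statistics undefined and are
reported as missing, never as 0. Brackets follow the printed cut-offs
(`perfect` ≤ 0.2 < `good` ≤ 0.3 < `adequate` ≤ 0.4 < `big_gap` ≤ 0.5 <
`severe_gap`), with closed upper edges; candidacy for the housekeeping ring
uses the *strict* inequality Gini < 0.3, so a gene at exactly 0.3 is classed
"good" but is not a candidate. The concentric filtration intersects the ring
with optional cross-condition, essentiality and conservation lists, in that
order. Essentiality enrichment is a one-sided (greater) Fisher exact test —
enrichment, not depletion, is the question — whose p-value equals the
hypergeometric upper tail; the odds ratio is the sample cross-product ratio
so that a set with the universe's essential fraction scores exactly 1.

## TF activity

ChIP-seq peak apexes are clustered along each chromosome: sorted by position,
a new cluster starts whenever the apex-to-apex gap reaches 200 bases (a gap
of exactly 200 splits, 199 merges; only apexes are retained, so gaps are
measured apex-to-apex). Clusters binding more than 70 distinct TFs are
removed as HOT (high-occupancy-target) sites — exactly 70 is kept — and
single-TF clusters are removed as likely spurious.

A surviving cluster, located at the mean of its member apexes, is assigned to
the gene with the nearest TSS if (i) that distance $d_1$ is at most 2,000
bases and (ii) the next-nearest TSS satisfies $d_2 \ge 1.5\, d_1$. Distance
is unstranded, $|{\rm apex} - {\rm TSS}|$, since strand plays no role in the
assignment rule. Two degenerate cases are resolved explicitly: $d_1 = 0$
(apex exactly on a TSS) is assigned regardless of the ratio, which is
undefined there, and an exact $d_1 = d_2$ tie is left unassigned as
ambiguous.

Peak signals are rank-normalized to cumulative probabilities within each
(TF, stage) experiment — ascending ranks over $N$ peaks divided by $N$,
average ranks for ties, so the strongest peak maps to 1. The predictor matrix
takes, per (gene, TF), the maximum normalized signal over all peaks of that
TF in clusters assigned to the gene. Genes never targeted by a surviving
cluster carry no predictor information and are excluded from the regression
rows. An option keeps embryonic-stage experiments only for TFs lacking
post-embryonic data.

Each cell type gets its own L1-regularized (lasso) linear model of
$\log(1 + \text{scaled TPM})$ on the predictor matrix, with intercept,
standardized predictors, and the penalty chosen at the minimum of 20-fold
cross-validated mean squared error (glmnet; fold assignment is seeded). The
log1p transform stabilizes the heavy-tailed TPM scale and can be switched off
(`response = "raw"`); the elastic-net mixing parameter is exposed
(`enet_alpha`, default 1 = lasso). Negative coefficients are clipped to zero
for the activity map — only activating regulation is modeled — while raw
coefficients are retained. A constant response vector short-circuits to the
intercept-only fit with zero coefficients. An *association* requires a
positive clipped coefficient **and** robust expression of the TF gene in that
cell type; the per-cell-type reading of "detectably expressed" feeds the
association table, while the clipped coefficient matrix itself is left
unfiltered so both readings remain available.

Cell-type dendrograms use Euclidean distance and Ward.D2 linkage
(`stats::hclust`). Baker's gamma between two trees is the Spearman
correlation of leaf-pair merge depths — for each pair, the highest number of
clusters at which the pair is still together — implemented over `cutree` and
cross-checked in the tests against an explicit merge-matrix traversal.

## Cell-cell communication

Pseudobulk expression for communication is the per-cell-type mean of
$\log(1 + \mathrm{CPM})$. The communication score of (pair, sender, receiver)
is the geometric mean of ligand expression in the sender and receptor
expression in the receiver; a gene missing from the matrix scores 0 with a
warning, keeping the tensor shape intact.

Significance uses a label-shuffle null: cell-to-cell-type assignments are
permuted (preserving per-type cell counts), the full aggregation and scoring
are recomputed per permutation, and
$p = (1 + \#\{\text{null} \ge \text{obs}\}) / (n_{\rm perm} + 1)$ — the
add-one estimator avoids $p = 0$ and bounds p below by $1/(n_{\rm perm}+1)$.
Shuffling labels rather than gene expression is the null matched to the
question "is this score cell-type-specific?": under it, a gene with
type-independent expression yields exactly uniform p-values, which the
calibration tests confirm. Scores with $p < 0.05$ (raw, matching the
method's convention; an optional Benjamini–Hochberg mode is off by default)
form the 3-D communication tensor; masked entries are exactly 0.

The tensor is factorized by non-negative canonical polyadic decomposition
using hierarchical alternating least squares (HALS): each factor column is
updated in closed form against the residual and clipped at zero, with a
collapsed column re-seeded to a small value. Runs start from uniform random
factors (each restart separately seeded), iterate to a relative error change
below $10^{-9}$ or 300 iterations, and the best of `n_restarts` by
reconstruction error is kept. Loadings are reported with unit Euclidean norm
per mode; the scale of each component lives in a weight vector, and
components are sorted by decreasing weight so factor order is deterministic.
`rank_scan()` warm-starts each rank from the previous solution plus one
random component — guaranteeing a non-increasing error curve — and suggests
the rank at the maximum second difference of the error (the elbow). Rank
remains a user choice; the scan is advisory.

## The synthetic-data generator

The generator emulates the statistical structure every stage assumes, with a
machine-readable ground truth. Counts are negative binomial in the
mean/dispersion parameterization (`nb_dispersion = 0.3`, the standard
overdispersed model for droplet UMI data), with per-cell log-normal library
factors (σ = 0.35). The default atlas is 12 cell types × 150 cells and 2,000
genes — large enough for stable recovery, small enough that the full test
suite runs in minutes; the cell types form 4 groups of 3, a planted
hierarchy.

Gene roles and effect sizes (all exposed in `sim_config()`; the source data
offers no quantitative effect sizes, so these are the package's own choices,
fixed once):

* **Housekeeping genes** (150): one log-normal mean per gene
  (median 2 counts/cell, σ = 0.5), identical across types.
* **Markers** (25/type): 5× elevated in one type, silent elsewhere.
* **TF genes** (40): broadly detected, with heavy type-level log-normal
  noise (σ = 1.0, truncated below at 0.25×) that carries *no* group
  structure — so TF expression alone is a poor predictor of cell identity,
  while TF *activity* is group-structured by construction. Each TF is active
  in the types of one group with weights U(0.8, 1.2); each planted target
  gene is bound by two random TFs and gains
  `tf_activity_scale` × weight × signal expression in the active types.
  Binding is realized as peaks within 2 kb of the target TSS, placed so the
  1.5× ambiguity rule holds by construction on a synthetic genome whose TSS
  spacing makes that possible (generation fails loudly otherwise).
* **Background genes** (the remainder): active in a random 55% subset of
  groups with strong type-level spread (log-normal σ = 1.2, truncated below
  at 0.4×), silent in inactive groups. Truncating the jitter from below makes
  "active" mean "detectable", which keeps each cell type's gene-detection
  curve saturating at the study scale; the wide upper tail keeps the Gini
  coefficient of a typical background gene well above the housekeeping ring.
* **LR pairs** (60, 3 signatures of 8 pairs): signature ligands are boosted
  (`lr_boost = 60`) in the sender group's types and receptors in the receiver
  group's types. Non-signature pairs have a cell-type-independent baseline
  set near the detection limit (median 0.008 counts/cell): signalling genes
  are lowly transcribed outside their producing tissues, and at this level
  their *measured* expression equality is poor, so they do not contaminate
  the housekeeping ring — while still being globally detected, which keeps
  the permutation null exactly calibrated.
* **Decoys**: HOT regions with 75 distinct TF labels 2 bp apart (the peak
  table may contain assayed-only TF ids beyond the modeled 40, as real
  compendia do; HOT filtering removes them before any downstream step) and
  isolated single-TF peaks, both recorded in the truth object.

Floors for "off" states are effectively zero (10⁻⁵ relative), reflecting
ambient-decontaminated input data.

What the generator does **not** emulate — and therefore what passing
recovery tests cannot certify on real data: ambient RNA and doublets, batch
effects, UMAP/clustering artifacts upstream of the labels, read-level noise,
multi-subunit receptor complexes, strand- or chromatin-context effects on
TF binding, and repressive regulation (negatives are clipped here as in the
modeled workflow).

## Reproducibility and numerics

Every stochastic routine takes a seed and derives independent streams per
(stage, cell type, size, iteration) through a small integer hash, so
individual pieces are reproducible in isolation and the full pipeline is
bit-identical across runs: the test suite hashes two complete pipeline runs
and compares (the run manifest's wall-clock fields and the PDF report's
embedded creation date are the only exclusions). Problem sizes used by the
validation suite: the default 12 × 150-cell atlas; 200 simulation replicates
(×1,000 bootstrap resamples) for interval coverage; 500 permutations for
calibration and recovery; rank scans over ranks 1–5 with 10 seeds.

## Known limitations

G\_MAX extrapolates the fitted asymptote: on data whose detection curve has
a long sub-detection tail (many genes just below one expected count at full
size), the log-logistic plateau overestimates the detected-gene total, and
the coverage fraction is correspondingly optimistic. The HALS decomposition
is a local optimizer; restarts mitigate but do not eliminate dependence on
initialization at higher ranks. Associations inherit the bulk nature of the
binding data: a TF active only in rare cell types can be mis-scored. The
pipeline treats cell-type labels as given; label noise propagates to every
stage.
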
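# wbatlas

Analysis toolkit for whole-body single-cell RNA-seq atlases of small
metazoans (the motivating system is the adult *Caenorhabditis elegans*
hermaphrodite, ~180 cell types profiled by droplet scRNA-seq). Starting from
a gene-by-cell count matrix with cell-type labels, plus ChIP-seq peak and
ligand-receptor (LR) annotations, the package answers five questions a
whole-body atlas raises:

1. **What does each cell type express?** Size-factor-normalized counts are
   aggregated into *scaled TPM* profiles (each cell-type column sums to
   10⁶), with within-type bootstrap confidence intervals; a gene is
   *robustly expressed* where the 95% lower bound is positive.
2. **How much of each transcriptome was captured?** Down-sampling curves of
   detected genes vs cells are fitted with a three-parameter log-logistic
   `f(x) = d / (1 + exp(b (log x − log e)))`, giving the predicted gene
   total G_MAX = `d`, the half-coverage cell count `e` (with `f(e) = d/2`),
   and the covered fraction `f(N)/d`.
3. **Which genes are housekeeping?** Moment skewness `g₁ = m₃/m₂^{3/2}` of
   percent-cells-expressing, and the Gini coefficient
   `G = Σᵢⱼ|xᵢ−xⱼ| / (2n²x̄)` of scaled TPM across cell types, with the
   printed equality brackets and a concentric filtration (Gini < 0.3 ∩
   cross-condition ∩ essential ∩ conserved) plus one-sided Fisher
   enrichment tests.
4. **Which TFs drive cell identity?** ChIP-seq peaks are clustered with a
   200-bp gap rule; HOT clusters (>70 TFs) and single-TF clusters are
   dropped; clusters map to the nearest TSS within 2 kb when the runner-up
   TSS is ≥1.5× farther; rank-normalized binding signals feed one lasso
   regression of log1p(scaled TPM) per cell type (20-fold CV penalty,
   negative coefficients clipped). Activity- and expression-based cell-type
   dendrograms (Ward.D2) are compared by Baker's gamma.
5. **Which cells talk, and through which ligand-receptor pairs?** The
   communication score is the geometric mean of ligand (sender) and
   receptor (receiver) pseudobulk log1p-CPM; a label-shuffle permutation
   test keeps scores with p < 0.05 in a pair × sender × receiver tensor,
   decomposed by non-negative canonical polyadic factorization into
   communication signatures.

A synthetic-data generator (`sim_config()` / `simulate_atlas()`) plants all
of this structure — housekeeping genes, TF regulons realized as both peaks
and expression, sender/receiver LR signatures, decoy HOT regions — with a
machine-readable ground truth, so every stage is validated by recovery
rather than by fixture.

## Worked example

```r
library(wbatlas)

atlas <- simulate_atlas(sim_config(seed = 1))
atlas
#> Synthetic atlas: 2000 genes x 1800 cells, 12 cell types
#>   peaks: 765
#>   LR pairs: 60
#>   planted housekeeping genes: 150

prof <- bootstrap_profile(atlas$counts, atlas$cell_labels, n_boot = 1000, seed = 1)
prof
#> Cell-type expression profile: 2000 genes x 12 cell types
#>   bootstrap: 1000 resamples; CI levels: 0.95, 0.8
#>   robustly expressed genes per type: median 1137

scores <- gene_consistency_scores(prof$scaled_tpm,
                                  percent_expressed(atlas$counts, atlas$cell_labels))
housekeeping_candidates(scores)
#> Housekeeping candidate filtration (Gini < 0.3 ):
#>   consistent       158 genes

fit_log_logistic(downsample_curve(atlas$counts, atlas$cell_labels, "ct01", seed = 1))
#> Log-logistic saturation fit (ct01)
#>   G_MAX (d) = 1218.4 genes; half-coverage at e = 0.4 cells; b = -0.703; RSS = 417

pc <- assign_targets(filter_clusters(cluster_peaks(normalize_signals(atlas$peaks))),
                     atlas$gene_annotation)
fit_tf_models(build_predictor_matrix(pc), prof, seed = 1)
#> TF activity: 40 TFs x 12 cell types
#>   positive-coefficient associations: 122 ( 122 with robustly expressed TF )
#>   20-fold CV MSE: median 0.2873

pt <- permutation_test(atlas$counts, atlas$cell_labels, atlas$lr_pairs,
                       n_perm = 500, seed = 1)
tensor <- build_tensor(pt$scores, pt$p_values, lr_class = atlas$lr_pairs$class)
tensor
#> Communication tensor: 60 LR pairs x 12 senders x 12 receivers
#>   478 of 8640 entries significant at alpha = 0.05

decompose(tensor, rank = 3, seed = 1)
#> CCI signatures: rank 3, relative reconstruction error 0.0744
#>   component weights: 22, 21.4, 20.7
```

Reading these numbers: of the 2,000 simulated genes, a median of 1,137 per
cell type are robustly expressed; the Gini < 0.3 ring holds 158 genes, close
to the 150 planted housekeeping genes. The saturation fit says ct01's
detected-gene count plateaus near 1,218 genes, reached halfway with under a
cell's worth of sampling — detection is easy in this simulation because
"off" genes are truly silent. The lasso finds 122 positive TF–cell-type
coefficients (the planted truth has 120), and the rank-3 factorization of
the 478 significant communication scores reconstructs the tensor to within
7% relative error, one factor per planted signature.

The same stages run as a pipeline with caching, a run manifest, and a text +
PDF report:

```r
run_pipeline(pipeline_config("out", seed = 1))
```

or from a shell via the thin wrapper `exec/atlas-infer`
(`atlas-infer run --out out --seed 1`).

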
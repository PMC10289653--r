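#' Configuration for the synthetic atlas generator
#'
#' Defines the size and effect-size structure of a simulated whole-body atlas:
#' a negative-binomial gene-by-cell count matrix over `n_cell_types` cell types
#' organized into `n_groups` related groups (a planted cell-type hierarchy),
#' with planted housekeeping genes, per-type marker genes, TF-to-cell-type
#' activity realized both as ChIP-seq peak signal and as expression response,
#' and ligand-receptor communication signatures.
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type integer, or integer vector of length `n_cell_types`.
#' @param n_genes total number of genes.
#' @param n_housekeeping number of planted housekeeping genes (equal mean
#'   expression in every cell type).
#' @param n_markers_per_type genes elevated in exactly one cell type.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); typical droplet UMI data sits near 0.2-0.5.
#' @param libsize_lognormal_mu,libsize_lognormal_sigma log-normal parameters of
#'   the per-cell library-size factor.
#' @param n_tfs number of modeled transcription factors (TF genes are part of
#'   the gene universe and broadly expressed).
#' @param targets_per_tf expected regulatory targets per TF.
#' @param tf_activity_scale multiplier on the expression response of TF targets
#'   in cell types where the TF is active.
#' @param n_lr_pairs number of ligand-receptor pairs emitted.
#' @param n_signatures number of planted communication signatures.
#' @param n_groups number of cell-type groups in the planted hierarchy (TF
#'   activity and background expression are group-structured).
#' @param genome_n_chroms,chrom_length_bp synthetic genome geometry.
#' @param n_decoy_hot number of decoy HOT regions (>70 distinct TFs within one
#'   cluster) planted in the peak table.
#' @param n_singletons number of isolated single-TF peaks planted.
#' @param marker_fold,hk_mean,lr_boost free effect-size parameters: fold
#'   elevation of markers, mean expression of housekeeping genes, and the
#'   multiplicative boost of signature ligands/receptors in their sender /
#'   receiver types.
#' @param seed integer seed controlling every random draw of the generator.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cell_types = 12,
                       cells_per_type = 150,
                       n_genes = 2000,
                       n_housekeeping = 150,
                       n_markers_per_type = 25,
                       nb_dispersion = 0.3,
                       libsize_lognormal_mu = 0,
                       libsize_lognormal_sigma = 0.35,
                       n_tfs = 40,
                       targets_per_tf = 15,
                       tf_activity_scale = 3,
                       n_lr_pairs = 60,
                       n_signatures = 3,
                       n_groups = 4,
                       genome_n_chroms = 6,
                       chrom_length_bp = 4e6,
                       n_decoy_hot = 2,
                       n_singletons = 15,
                       marker_fold = 5,
                       hk_mean = 2,
                       lr_boost = 60,
                       seed = 1) {
  cfg <- list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type = as.integer(if (length(cells_per_type) == 1)
      rep(cells_per_type, n_cell_types) else cells_per_type),
    n_genes = as.integer(n_genes),
    n_housekeeping = as.integer(n_housekeeping),
    n_markers_per_type = as.integer(n_markers_per_type),
    nb_dispersion = nb_dispersion,
    libsize_lognormal_mu = libsize_lognormal_mu,
    libsize_lognormal_sigma = libsize_lognormal_sigma,
    n_tfs = as.integer(n_tfs),
    targets_per_tf = as.integer(targets_per_tf),
    tf_activity_scale = tf_activity_scale,
    n_lr_pairs = as.integer(n_lr_pairs),
    n_signatures = as.integer(n_signatures),
    n_groups = as.integer(n_groups),
    genome_n_chroms = as.integer(genome_n_chroms),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_decoy_hot = as.integer(n_decoy_hot),
    n_singletons = as.integer(n_singletons),
    marker_fold = marker_fold,
    hk_mean = hk_mean,
    lr_boost = lr_boost,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (n_cell_types < 1 || n_genes < 1 || any(cells_per_type < 1))
      stop("configuration error: all counts must be >= 1")
    if (length(cells_per_type) != n_cell_types)
      stop("configuration error: cells_per_type must have one entry per cell type")
    if (nb_dispersion <= 0) stop("configuration error: dispersion must be > 0")
    if (tf_activity_scale <= 0) stop("configuration error: tf_activity_scale must be > 0")
    n_targets <- ceiling(n_tfs * targets_per_tf / 2)
    reserved <- n_housekeeping + n_cell_types * n_markers_per_type + n_tfs +
      2L * n_lr_pairs + n_targets
    if (reserved > n_genes)
      stop("configuration error: n_genes too small for the requested ",
           "housekeeping/marker/TF/LR gene roles (need >= ", reserved, ")")
    if (n_signatures > n_lr_pairs)
      stop("configuration error: n_signatures > n_lr_pairs")
    if (n_groups < 1 || n_groups > n_cell_types)
      stop("configuration error: n_groups must be in [1, n_cell_types]")
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic atlas configuration\n")
  cat(sprintf("  %d cell types (%d groups) x %s cells; %d genes\n",
              x$n_cell_types, x$n_groups,
              paste(range(x$cells_per_type), collapse = "-"), x$n_genes))
  cat(sprintf("  planted: %d housekeeping, %d markers/type, %d TFs (~%d targets each), %d LR pairs (%d signatures)\n",
              x$n_housekeeping, x$n_markers_per_type, x$n_tfs,
              x$targets_per_tf, x$n_lr_pairs, x$n_signatures))
  cat(sprintf("  NB dispersion %.3g; library-size lognormal(%.3g, %.3g); seed %d\n",
              x$nb_dispersion, x$libsize_lognormal_mu, x$libsize_lognormal_sigma, x$seed))
  invisible(x)
}
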
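## TF-activity inference from ChIP-seq binding and cell-type expression.
##
## Peaks (apex positions) are clustered along each chromosome with a 200-bp
## gap rule; clusters binding a single TF (spurious) or more than 70 distinct
## TFs (HOT sites, not tissue-specific) are removed; surviving clusters are
## assigned to the gene with the nearest TSS when that TSS is within 2 kb and
## the next-nearest TSS is at least 1.5x farther. Peak signals are rank
## normalized within each (TF, stage) experiment; the gene x TF matrix of
## maximal normalized signals is the predictor matrix for one L1-regularized
## regression per cell type of log1p(scaled TPM) on binding, with a 20-fold
## cross-validated penalty. Negative coefficients are clipped to zero for the
## activity map (raw coefficients are retained).

#' Cluster peaks along the genome
#'
#' Per chromosome, peaks are sorted by apex and accumulated into a cluster
#' until a gap of `gap` bases or more between consecutive apexes is
#' encountered, at which point a new cluster starts. Clusters never span
#' chromosomes.
#'
#' @param peaks data.frame with columns chrom, apex, tf, stage, signal
#'   (0-based apex positions).
#' @param gap minimal apex-to-apex distance that separates clusters.
#' @return object of class `peak_clusters`: `peaks` (input rows plus
#'   `cluster` id, sorted by chrom/apex) and `clusters` (one row per cluster:
#'   cluster, chrom, mean_apex, n_peaks, n_tfs, target_gene = NA).
#' @export
cluster_peaks <- function(peaks, gap = 200) {
  stopifnot(all(c("chrom", "apex", "tf") %in% names(peaks)))
  if (any(peaks$apex < 0)) stop("input error: negative apex position")
  ord <- order(peaks$chrom, peaks$apex, peaks$tf)
  p <- peaks[ord, , drop = FALSE]
  new_chrom <- c(TRUE, p$chrom[-1] != p$chrom[-nrow(p)])
  gap_hit <- c(TRUE, diff(p$apex) >= gap) | new_chrom
  p$cluster <- cumsum(gap_hit)
  cl <- do.call(rbind, lapply(split(p, p$cluster), function(d)
    data.frame(cluster = d$cluster[1], chrom = d$chrom[1],
               mean_apex = mean(d$apex), n_peaks = nrow(d),
               n_tfs = length(unique(d$tf)), target_gene = NA_character_,
               stringsAsFactors = FALSE)))
  rownames(cl) <- NULL
  structure(list(peaks = p, clusters = cl, gap = gap), class = "peak_clusters")
}

#' Remove HOT and single-TF clusters
#'
#' Keeps clusters whose distinct-TF count lies in `[min_tfs, max_tfs]`:
#' clusters with more than `max_tfs` TFs are high-occupancy-target (HOT) sites
#' unlikely to reflect tissue-specific binding; single-TF clusters are likely
#' spurious.
#'
#' @param pc a `peak_clusters` object.
#' @param max_tfs maximum distinct TFs (inclusive).
#' @param min_tfs minimum distinct TFs (inclusive).
#' @return the filtered `peak_clusters`, with a `removed` attribute counting
#'   removals by reason.
#' @export
filter_clusters <- function(pc, max_tfs = 70, min_tfs = 2) {
  stopifnot(inherits(pc, "peak_clusters"))
  hot <- pc$clusters$n_tfs > max_tfs
  few <- pc$clusters$n_tfs < min_tfs
  keep_ids <- pc$clusters$cluster[!hot & !few]
  pc$peaks <- pc$peaks[pc$peaks$cluster %in% keep_ids, , drop = FALSE]
  pc$clusters <- pc$clusters[!hot & !few, , drop = FALSE]
  attr(pc, "removed") <- c(hot = sum(hot), single_tf = sum(few))
  pc
}

#' Assign peak clusters to target genes by TSS proximity
#'
#' A cluster (located at the mean apex of its peaks) is assigned to the gene
#' with the closest TSS on the same chromosome iff that distance d1 is at most
#' `max_dist` and the distance d2 to the next-closest TSS satisfies
#' `d2 >= ratio * d1`. A cluster exactly on a TSS (d1 = 0) is assigned
#' regardless of the ratio; an exact d1 = d2 tie is left unassigned.
#'
#' @param pc a `peak_clusters` object.
#' @param tss_table data.frame with columns gene, chrom, tss (one TSS per
#'   gene).
#' @param max_dist maximal cluster-to-TSS distance (bases).
#' @param ratio minimal d2/d1 disambiguation factor.
#' @return the `peak_clusters` with `clusters$target_gene` filled (NA where
#'   unassigned).
#' @export
assign_targets <- function(pc, tss_table, max_dist = 2000, ratio = 1.5) {
  stopifnot(inherits(pc, "peak_clusters"),
            all(c("gene", "chrom", "tss") %in% names(tss_table)))
  if (anyDuplicated(tss_table$gene)) stop("tss_table must have one TSS per gene")
  by_chrom <- split(tss_table, tss_table$chrom)
  cl <- pc$clusters
  cl$target_gene <- NA_character_
  for (i in seq_len(nrow(cl))) {
    tt <- by_chrom[[cl$chrom[i]]]
    if (is.null(tt) || nrow(tt) == 0) next  # no annotation on this chromosome
    d <- abs(cl$mean_apex[i] - tt$tss)
    o <- order(d)
    d1 <- d[o[1]]
    if (d1 > max_dist) next
    if (nrow(tt) >= 2) {
      d2 <- d[o[2]]
      if (d1 == d2) next            # ambiguous target
      if (d1 > 0 && d2 < ratio * d1) next
    }
    cl$target_gene[i] <- tt$gene[o[1]]
  }
  pc$clusters <- cl
  pc
}

#' Rank-normalize peak signals within each experiment
#'
#' Within every (TF, stage) experiment of N peaks, the normalized signal is
#' `rank / N` with ascending ranks and average ranks for ties, so the
#' strongest peak maps to 1.
#'
#' @param peaks data.frame with columns tf, stage, signal (positive).
#' @return the peaks with a `norm_signal` column appended.
#' @export
normalize_signals <- function(peaks) {
  stopifnot(all(c("tf", "stage", "signal") %in% names(peaks)))
  if (any(peaks$signal <= 0)) stop("input error: non-positive peak signal")
  key <- paste(peaks$tf, peaks$stage, sep = "\r")
  peaks$norm_signal <- NA_real_
  for (k in unique(key)) {
    idx <- which(key == k)
    peaks$norm_signal[idx] <- rank(peaks$signal[idx]) / length(idx)
  }
  peaks
}

#' Keep embryonic-stage experiments only for TFs lacking post-embryonic data
#'
#' @param peaks peak data.frame with tf and stage columns.
#' @param embryonic_stages stage labels counted as embryonic.
#' @return the filtered peak table.
#' @export
filter_stage_precedence <- function(peaks, embryonic_stages = c("EM", "embryo")) {
  is_em <- peaks$stage %in% embryonic_stages
  has_post <- unique(peaks$tf[!is_em])
  peaks[!is_em | !(peaks$tf %in% has_post), , drop = FALSE]
}

#' Gene x TF predictor matrix of maximal normalized binding signal
#'
#' `X[g, t]` is the maximum `norm_signal` over all peaks of TF t belonging to
#' clusters assigned to gene g (multiple peaks of one TF in a cluster, or
#' multiple clusters per gene, collapse by max); 0 where the TF does not bind.
#'
#' @param pc a `peak_clusters` after [assign_targets()], whose peaks carry
#'   `norm_signal` (see [normalize_signals()]).
#' @return dense gene x TF matrix (rows: genes with at least one assigned
#'   cluster).
#' @export
build_predictor_matrix <- function(pc) {
  stopifnot(inherits(pc, "peak_clusters"))
  if (is.null(pc$peaks$norm_signal))
    stop("peaks lack norm_signal; run normalize_signals() first")
  cl <- pc$clusters[!is.na(pc$clusters$target_gene), , drop = FALSE]
  if (!nrow(cl)) stop("no assigned clusters")
  p <- pc$peaks[pc$peaks$cluster %in% cl$cluster, , drop = FALSE]
  p$gene <- cl$target_gene[match(p$cluster, cl$cluster)]
  genes <- sort(unique(p$gene))
  tfs <- sort(unique(p$tf))
  X <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  agg <- stats::aggregate(norm_signal ~ gene + tf, data = p, FUN = max)
  X[cbind(match(agg$gene, genes), match(agg$tf, tfs))] <- agg$norm_signal
  X
}

#' Per-cell-type lasso regression of expression on TF binding
#'
#' For each cell type k, fits `log1p(scaled_tpm[, k]) ~ X` by L1-regularized
#' least squares with an intercept; the penalty is chosen at the minimum of
#' `folds`-fold cross-validated mean squared error. Negative coefficients are
#' clipped to zero in the activity matrix (raw coefficients are kept).
#' An association (tf, cell type) is called when the clipped coefficient is
#' positive and the TF gene is robustly expressed in that cell type.
#'
#' @param X gene x TF predictor matrix from [build_predictor_matrix()].
#' @param profile a `cell_type_profile`; rows of `X` are intersected with its
#'   genes.
#' @param folds cross-validation folds.
#' @param seed integer seed (fold assignment).
#' @param response `"log1p"` (default) or `"raw"` response transform.
#' @param enet_alpha elastic-net mixing parameter passed to glmnet; 1 (the
#'   default) is the pure lasso.
#' @return object of class `tf_activity` with `beta` (clipped, TF x cell
#'   type), `beta_raw`, `cv_mse` (per cell type), and `associations`
#'   (data.frame tf, cell_type, beta).
#' @export
fit_tf_models <- function(X, profile, folds = 20, seed = 1,
                          response = c("log1p", "raw"), enet_alpha = 1) {
  response <- match.arg(response)
  stopifnot(inherits(profile, "cell_type_profile"))
  genes <- intersect(rownames(X), rownames(profile$scaled_tpm))
  if (length(genes) < folds)
    stop("configuration error: fewer predictor genes (", length(genes),
         ") than folds (", folds, ")")
  X <- X[genes, , drop = FALSE]
  types <- colnames(profile$scaled_tpm)
  beta_raw <- matrix(0, ncol(X), length(types),
                     dimnames = list(colnames(X), types))
  cv_mse <- setNames(numeric(length(types)), types)
  for (k in types) {
    y <- profile$scaled_tpm[genes, k]
    if (response == "log1p") y <- log1p(y)
    if (stats::var(y) < 1e-18) {
      ## constant response: intercept-only model, no TF carries signal
      beta_raw[, k] <- 0
      cv_mse[k] <- 0
      next
    }
    set.seed(derive_seed(seed, "tfmodel", k))
    foldid <- sample(rep(seq_len(folds), length.out = length(y)))
    cv <- glmnet::cv.glmnet(X, y, alpha = enet_alpha, foldid = foldid,
                            standardize = TRUE,
                            grouped = length(y) >= 3 * folds)
    i <- which(cv$lambda == cv$lambda.min)
    beta_raw[, k] <- as.numeric(coef(cv, s = "lambda.min"))[-1]
    cv_mse[k] <- cv$cvm[i]
  }
  beta <- pmax(beta_raw, 0)
  assoc <- which(beta > 0, arr.ind = TRUE)
  associations <- data.frame(tf = rownames(beta)[assoc[, 1]],
                             cell_type = colnames(beta)[assoc[, 2]],
                             beta = beta[assoc], stringsAsFactors = FALSE)
  if (!is.null(profile$robust_mask)) {
    expressed <- mapply(function(tf, k) {
      tf %in% rownames(profile$robust_mask) && profile$robust_mask[tf, k]
    }, associations$tf, associations$cell_type)
    associations <- associations[as.logical(expressed), , drop = FALSE]
    rownames(associations) <- NULL
  }
  structure(list(beta = beta, beta_raw = beta_raw, cv_mse = cv_mse,
                 associations = associations, folds = folds,
                 response = response),
            class = "tf_activity")
}

#' @export
print.tf_activity <- function(x, ...) {
  cat("TF activity:", nrow(x$beta), "TFs x", ncol(x$beta), "cell types\n")
  cat("  positive-coefficient associations:", sum(x$beta > 0),
      "(", nrow(x$associations), "with robustly expressed TF )\n")
  cat(sprintf("  %d-fold CV MSE: median %.4g\n", x$folds,
              stats::median(x$cv_mse)))
  invisible(x)
}
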
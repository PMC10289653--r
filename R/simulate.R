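## Synthetic whole-body atlas generator.
##
## The generator plants four kinds of structure, each consumed by a downstream
## stage as a recovery oracle:
##   * housekeeping genes: equal negative-binomial mean in every cell type;
##   * marker genes: elevated in one cell type, near-silent elsewhere;
##   * TF regulons: each TF is a broadly expressed gene, active in the cell
##     types of one group; its targets gain expression there, and binding is
##     realized as ChIP-seq peaks near the target TSS;
##   * LR signatures: ligand genes boosted in sender types, receptors in
##     receiver types, for a planted subset of ligand-receptor pairs.
## Background genes are active in a random subset of cell-type groups, which
## both creates the planted cell-type hierarchy and keeps the Gini score of a
## typical non-housekeeping gene high.

#' Simulate a labeled count matrix with planted structure
#'
#' Draws a gene-by-cell negative-binomial count matrix over the configured
#' cell types, with per-cell log-normal library-size factors. Fills the parts
#' of the ground-truth record that concern expression (housekeeping set, TF
#' activity weights, TF target sets).
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_atlas`: a list with `counts` (sparse
#'   dgCMatrix, genes x cells), `cell_labels` (named character), `truth`, the
#'   `config`, and internal state used by [simulate_peaks()] and
#'   [simulate_lr_structure()].
#' @export
simulate_counts <- function(config) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$seed, "counts"))
  K <- config$n_cell_types
  G <- config$n_genes

  types <- sprintf("ct%02d", seq_len(K))
  ## contiguous groups: split types as evenly as possible
  group_of <- sort(rep(seq_len(config$n_groups), length.out = K))
  names(group_of) <- types

  genes <- sprintf("g%05d", seq_len(G))
  n_targets <- ceiling(config$n_tfs * config$targets_per_tf / 2)

  ## gene role layout (disjoint blocks)
  idx <- 0L
  take <- function(n) { r <- idx + seq_len(n); idx <<- idx + n; r }
  i_hk <- take(config$n_housekeeping)
  i_marker <- take(K * config$n_markers_per_type)
  i_tf <- take(config$n_tfs)
  i_lig <- take(config$n_lr_pairs)
  i_rec <- take(config$n_lr_pairs)
  i_target <- take(n_targets)
  i_bg <- if (idx < G) (idx + 1L):G else integer(0)

  mu <- matrix(1e-5, G, K, dimnames = list(genes, types))

  ## housekeeping: one mean per gene, identical across types
  if (length(i_hk)) mu[i_hk, ] <- rlnorm(length(i_hk), log(config$hk_mean), 0.5)

  ## markers: elevated in exactly one type
  if (length(i_marker)) {
    marker_type <- rep(seq_len(K), each = config$n_markers_per_type)
    base_m <- rlnorm(length(i_marker), log(0.8), 0.5)
    mu[i_marker, ] <- base_m * 1e-5
    mu[cbind(i_marker, marker_type)] <- base_m * config$marker_fold
  }

  ## TF genes: broadly detected, but with type-level noise that carries no
  ## group structure, so TF expression alone is a poor guide to cell identity
  if (length(i_tf)) {
    base_tf <- rlnorm(length(i_tf), log(1.5), 0.3)
    mu[i_tf, ] <- base_tf * matrix(pmax(rlnorm(length(i_tf) * K, 0, 1.0), 0.25),
                                   length(i_tf), K)
  }

  ## LR genes: type-independent baseline near the detection limit (signalling
  ## genes are lowly transcribed outside their producing tissues); signature
  ## boosts lift the relevant types well above it later
  i_lr <- c(i_lig, i_rec)
  if (length(i_lr)) {
    base_lr <- rlnorm(length(i_lr), log(0.008), 0.3)
    mu[i_lr, ] <- base_lr
  }

  ## TF activity: each TF active in all cell types of one group
  tf_ids <- genes[i_tf]
  W <- matrix(0, config$n_tfs, K, dimnames = list(tf_ids, types))
  tf_group <- rep(seq_len(config$n_groups), length.out = config$n_tfs)
  for (t in seq_len(config$n_tfs)) {
    active <- which(group_of == tf_group[t])
    W[t, active] <- runif(length(active), 0.8, 1.2)
  }

  ## each target gene is bound (and regulated) by two distinct TFs
  target_ids <- genes[i_target]
  S <- matrix(0, n_targets, config$n_tfs, dimnames = list(target_ids, tf_ids))
  if (config$n_tfs >= 2) {
    for (p in seq_len(n_targets)) {
      pick <- sample.int(config$n_tfs, 2)
      S[p, pick] <- runif(2, 0.5, 1)
    }
  }
  mu[i_target, ] <- 0.3 + config$tf_activity_scale * (S %*% W)

  ## background: active in a random subset of groups (planted hierarchy)
  if (length(i_bg)) {
    b <- pmax(rlnorm(length(i_bg), log(0.8), 0.6), 0.3)
    act <- matrix(runif(length(i_bg) * config$n_groups) < 0.55,
                  length(i_bg), config$n_groups)
    for (j in seq_along(i_bg)) {
      on <- act[j, group_of]
      jit <- pmax(rlnorm(K, 0, 1.2), 0.4)
      mu[i_bg[j], ] <- ifelse(on, b[j] * jit, b[j] * 1e-5)
    }
  }

  ## draw counts type by type
  n_cells <- config$cells_per_type
  cells <- sprintf("c%05d", seq_len(sum(n_cells)))
  labels <- setNames(rep(types, n_cells), cells)
  lib <- rlnorm(sum(n_cells), config$libsize_lognormal_mu,
                config$libsize_lognormal_sigma)
  names(lib) <- cells
  size <- 1 / config$nb_dispersion

  counts <- matrix(0L, G, sum(n_cells), dimnames = list(genes, cells))
  for (k in seq_len(K)) {
    j <- which(labels == types[k])
    m <- mu[, k] %o% lib[j]
    counts[, j] <- rnbinom(length(m), size = size, mu = m)
  }
  ## guarantee positive column totals (a fully empty droplet would be
  ## discarded upstream in any real pipeline)
  empty <- which(colSums(counts) == 0)
  if (length(empty)) counts[sample.int(G, 1), empty] <- 1L
  counts <- as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
               "CsparseMatrix")

  truth <- list(
    housekeeping_genes = genes[i_hk],
    marker_genes = setNames(genes[i_marker],
                            if (length(i_marker)) types[rep(seq_len(K), each = config$n_markers_per_type)] else NULL),
    tf_activity_weights = W,
    tf_targets = setNames(lapply(seq_len(config$n_tfs),
                                 function(t) target_ids[S[, t] > 0]), tf_ids),
    tf_target_signal = S,
    lr_signatures = list(),
    decoy_hot_regions = data.frame(chrom = character(), start = integer(),
                                   end = integer(), stringsAsFactors = FALSE),
    singleton_peaks = character(),
    group_of = group_of
  )
  class(truth) <- "synthetic_truth"

  atlas <- list(counts = counts, cell_labels = labels, gene_annotation = NULL,
                peaks = NULL, lr_pairs = NULL, truth = truth, config = config,
                internal = list(mu = mu, lib = lib,
                                roles = list(hk = i_hk, marker = i_marker,
                                             tf = i_tf, lig = i_lig, rec = i_rec,
                                             target = i_target, bg = i_bg)))
  class(atlas) <- "synthetic_atlas"
  atlas
}

#' Simulate a gene annotation and ChIP-seq peak table
#'
#' Places one TSS per gene along the synthetic genome and emits, for every
#' planted (TF, target) relationship, a peak whose apex lies within 2 kb of the
#' target TSS and far enough from the next-nearest TSS that the 1.5x ambiguity
#' rule is satisfied. Additionally emits decoy HOT regions (clusters of more
#' than 70 distinct TFs) and isolated single-TF peaks, both recorded in the
#' ground truth so the cluster filters can be validated.
#'
#' @param atlas a `synthetic_atlas` from [simulate_counts()].
#' @param config the [sim_config()] used to build it.
#' @return the atlas with `gene_annotation` (data.frame: gene, chrom, tss,
#'   strand; 0-based coordinates) and `peaks` (data.frame: chrom, apex, tf,
#'   stage, signal) filled in, and truth updated.
#' @export
simulate_peaks <- function(atlas, config = atlas$config) {
  stopifnot(inherits(atlas, "synthetic_atlas"))
  set.seed(derive_seed(config$seed, "peaks"))
  genes <- rownames(atlas$counts)
  G <- length(genes)

  chroms <- sprintf("chr%s", as.roman(seq_len(config$genome_n_chroms)))
  chrom_of <- rep(chroms, length.out = G)
  per_chrom <- table(factor(chrom_of, levels = chroms))
  tss <- integer(G)
  for (ci in seq_along(chroms)) {
    n_on <- per_chrom[[ci]]
    spacing <- config$chrom_length_bp / (n_on + 1)
    pos <- round(seq_len(n_on) * spacing +
                   runif(n_on, -0.1 * spacing, 0.1 * spacing))
    tss[chrom_of == chroms[ci]] <- as.integer(pos)
  }
  annotation <- data.frame(gene = genes, chrom = chrom_of, tss = tss,
                           strand = sample(c("+", "-"), G, replace = TRUE),
                           stringsAsFactors = FALSE)

  ## the tightest TSS gap determines how far a peak may sit from its target
  ## while still passing both the 2 kb and the 1.5x rules
  gap_min <- min(vapply(split(annotation$tss, annotation$chrom),
                        function(p) min(diff(sort(p))), numeric(1)))
  delta_max <- floor(min(1200, gap_min / 2.6)) - 60
  if (delta_max < 50)
    stop("generation error: genome too small to place peaks without ",
         "violating the 1.5x TSS-ambiguity rule")

  S <- atlas$truth$tf_target_signal
  tf_ids <- colnames(S)
  rows <- list()
  for (p in seq_len(nrow(S))) {
    g <- rownames(S)[p]
    bound <- which(S[p, ] > 0)
    if (!length(bound)) next
    a <- annotation[annotation$gene == g, ]
    center <- a$tss + sample(seq(-delta_max, delta_max), 1)
    offs <- sample(seq(-40, 40), length(bound), replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = a$chrom, apex = as.integer(center + offs), tf = tf_ids[bound],
      stage = "YA", signal = round(10 * S[p, bound] * rlnorm(length(bound), 0, 0.15), 4),
      stringsAsFactors = FALSE)
  }

  ## pool of intergenic midpoints for decoys and singletons
  mids <- do.call(rbind, lapply(split(annotation, annotation$chrom), function(d) {
    p <- sort(d$tss)
    if (length(p) < 2) return(NULL)
    data.frame(chrom = d$chrom[1], pos = as.integer(round((p[-length(p)] + p[-1]) / 2)),
               stringsAsFactors = FALSE)
  }))
  rownames(mids) <- NULL
  need <- config$n_decoy_hot + config$n_singletons
  if (need > nrow(mids))
    stop("generation error: not enough intergenic space for decoys")
  pick <- mids[sample.int(nrow(mids), need), , drop = FALSE]

  decoy_regions <- data.frame(chrom = character(), start = integer(),
                              end = integer(), stringsAsFactors = FALSE)
  hot_n_tfs <- 75L  # strictly more than the 70-TF HOT threshold
  filler <- sprintf("zf%03d", seq_len(max(0, hot_n_tfs - length(tf_ids))))
  for (d in seq_len(config$n_decoy_hot)) {
    loc <- pick[d, ]
    tfs <- c(tf_ids, filler)[seq_len(hot_n_tfs)]
    apexes <- as.integer(loc$pos + seq(0, by = 2, length.out = hot_n_tfs) - hot_n_tfs)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = loc$chrom, apex = apexes, tf = tfs, stage = "YA",
      signal = round(rlnorm(hot_n_tfs, log(5), 0.3), 4), stringsAsFactors = FALSE)
    decoy_regions <- rbind(decoy_regions,
                           data.frame(chrom = loc$chrom, start = min(apexes),
                                      end = max(apexes), stringsAsFactors = FALSE))
  }

  singleton_ids <- character(0)
  if (config$n_singletons > 0) {
    loc <- pick[config$n_decoy_hot + seq_len(config$n_singletons), , drop = FALSE]
    tfs <- sample(tf_ids, config$n_singletons, replace = TRUE)
    sing <- data.frame(chrom = loc$chrom, apex = as.integer(loc$pos), tf = tfs,
                       stage = "YA", signal = round(rlnorm(config$n_singletons, log(3), 0.3), 4),
                       stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- sing
    singleton_ids <- paste0(sing$chrom, ":", sing$apex)
  }

  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  atlas$gene_annotation <- annotation
  atlas$peaks <- peaks[, c("chrom", "apex", "tf", "stage", "signal")]
  atlas$truth$decoy_hot_regions <- decoy_regions
  atlas$truth$singleton_peaks <- singleton_ids
  atlas
}

#' Plant ligand-receptor communication signatures
#'
#' Emits the ligand-receptor pair list and, for each planted signature, boosts
#' ligand expression in its sender cell types and receptor expression in its
#' receiver cell types by re-drawing the affected count rows from the boosted
#' negative-binomial means. Non-signature pairs keep a cell-type-independent
#' expression profile.
#'
#' @param atlas a `synthetic_atlas` from [simulate_counts()].
#' @param config the [sim_config()] used to build it.
#' @return the atlas with `lr_pairs` (data.frame: ligand, receptor, class) and
#'   updated counts/truth.
#' @export
simulate_lr_structure <- function(atlas, config = atlas$config) {
  stopifnot(inherits(atlas, "synthetic_atlas"))
  if (config$n_signatures > config$n_lr_pairs)
    stop("configuration error: n_signatures > n_lr_pairs")
  set.seed(derive_seed(config$seed, "lr"))
  roles <- atlas$internal$roles
  genes <- rownames(atlas$counts)
  ligands <- genes[roles$lig]
  receptors <- genes[roles$rec]
  classes <- c("membrane-bound", "ECM", "secreted")
  lr <- data.frame(ligand = ligands, receptor = receptors,
                   class = sample(classes, config$n_lr_pairs, replace = TRUE),
                   stringsAsFactors = FALSE)

  types <- colnames(atlas$internal$mu)
  group_of <- atlas$truth$group_of
  sigs <- list()
  if (config$n_signatures > 0) {
    per_sig <- max(1L, min(8L, config$n_lr_pairs %/% (2L * config$n_signatures)))
    boosted <- integer(0)
    for (s in seq_len(config$n_signatures)) {
      pair_idx <- (s - 1L) * per_sig + seq_len(per_sig)
      g_send <- ((s - 1L) %% config$n_groups) + 1L
      g_recv <- (s %% config$n_groups) + 1L
      senders <- types[group_of == g_send]
      receivers <- types[group_of == g_recv]
      mu <- atlas$internal$mu
      mu[lr$ligand[pair_idx], senders] <-
        mu[lr$ligand[pair_idx], senders] * (1 + config$lr_boost)
      mu[lr$receptor[pair_idx], receivers] <-
        mu[lr$receptor[pair_idx], receivers] * (1 + config$lr_boost)
      atlas$internal$mu <- mu
      boosted <- union(boosted, c(match(lr$ligand[pair_idx], genes),
                                  match(lr$receptor[pair_idx], genes)))
      sigs[[s]] <- list(senders = senders, receivers = receivers,
                        pairs = paste(lr$ligand[pair_idx], lr$receptor[pair_idx],
                                      sep = "_"))
    }
    ## re-draw boosted rows from the updated means
    size <- 1 / config$nb_dispersion
    lib <- atlas$internal$lib
    labels <- atlas$cell_labels
    block <- matrix(0L, length(boosted), ncol(atlas$counts))
    for (k in types) {
      j <- which(labels == k)
      m <- atlas$internal$mu[boosted, k] %o% lib[j]
      block[, j] <- rnbinom(length(m), size = size, mu = m)
    }
    counts <- atlas$counts
    counts[boosted, ] <- block
    atlas$counts <- methods::as(counts, "CsparseMatrix")
  }
  atlas$lr_pairs <- lr
  atlas$truth$lr_signatures <- sigs
  atlas
}

#' Generate a complete synthetic atlas
#'
#' Convenience wrapper running [simulate_counts()], [simulate_peaks()] and
#' [simulate_lr_structure()] in order.
#'
#' @param config a [sim_config()].
#' @return a complete `synthetic_atlas`.
#' @export
simulate_atlas <- function(config = sim_config()) {
  atlas <- simulate_counts(config)
  atlas <- simulate_peaks(atlas, config)
  simulate_lr_structure(atlas, config)
}

#' @export
print.synthetic_atlas <- function(x, ...) {
  cat("Synthetic atlas:", nrow(x$counts), "genes x", ncol(x$counts), "cells,",
      length(unique(x$cell_labels)), "cell types\n")
  if (!is.null(x$peaks)) cat("  peaks:", nrow(x$peaks), "\n")
  if (!is.null(x$lr_pairs)) cat("  LR pairs:", nrow(x$lr_pairs), "\n")
  cat("  planted housekeeping genes:", length(x$truth$housekeeping_genes), "\n")
  invisible(x)
}
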
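## Independent brute-force oracles and shared fixtures.
## Oracles deliberately use the most literal formulation of each definition
## (nested loops, pairwise sums, explicit set tracking) so they share no code
## path with the implementation they check.

## --- shared fixtures (built once per test run) -------------------------------

.fixtures <- new.env(parent = emptyenv())

## the default synthetic atlas (the study conditions), cached
default_atlas <- function() {
  if (is.null(.fixtures$atlas)) .fixtures$atlas <- simulate_atlas(sim_config(seed = 1))
  .fixtures$atlas
}

## its scaled-TPM point-estimate profile, cached
default_profile <- function() {
  if (is.null(.fixtures$profile)) {
    a <- default_atlas()
    .fixtures$profile <- aggregate_scaled_tpm(size_factor_normalize(a$counts),
                                              a$cell_labels)
  }
  .fixtures$profile
}

## a small random labeled count matrix for exactness checks
tiny_counts <- function(n_genes = 8, n_cells = 12, n_types = 3, seed = 42,
                        lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  m[, 1] <- pmax(m[, 1], 1)  # keep totals positive
  labels <- setNames(rep(sprintf("t%d", seq_len(n_types)), length.out = n_cells),
                     colnames(m))
  list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
       dense = m, labels = labels)
}

## --- oracles -----------------------------------------------------------------

oracle_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

oracle_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

oracle_percent_expressed <- function(dense, labels) {
  types <- sort(unique(labels))
  out <- matrix(0, nrow(dense), length(types),
                dimnames = list(rownames(dense), types))
  for (g in seq_len(nrow(dense))) for (k in types) {
    cells <- which(labels == k)
    out[g, k] <- 100 * sum(dense[g, cells] > 0) / length(cells)
  }
  out
}

## steps (i)-(v): subset, per-gene mean, divide by sum of means, times 1e6
oracle_scaled_tpm <- function(dense_norm, labels) {
  types <- sort(unique(labels))
  out <- matrix(0, nrow(dense_norm), length(types),
                dimnames = list(rownames(dense_norm), types))
  for (k in types) {
    sub <- dense_norm[, labels == k, drop = FALSE]
    mns <- apply(sub, 1, mean)
    out[, k] <- mns / sum(mns) * 1e6
  }
  out
}

oracle_log1p_cpm <- function(dense, labels) {
  types <- sort(unique(labels))
  e <- dense
  for (j in seq_len(ncol(dense))) e[, j] <- log1p(dense[, j] * 1e6 / sum(dense[, j]))
  out <- matrix(0, nrow(dense), length(types),
                dimnames = list(rownames(dense), types))
  for (k in types) out[, k] <- apply(e[, labels == k, drop = FALSE], 1, mean)
  out
}

## O(n^2) gap-graph connected components per chromosome
oracle_cluster <- function(peaks, gap = 200) {
  comp <- rep(NA_integer_, nrow(peaks))
  next_id <- 0L
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    adj <- matrix(FALSE, length(idx), length(idx))
    for (a in seq_along(idx)) for (b in seq_along(idx))
      adj[a, b] <- abs(peaks$apex[idx[a]] - peaks$apex[idx[b]]) < gap
    left <- seq_along(idx)
    while (length(left)) {
      grp <- left[1]
      repeat {
        grown <- unique(c(grp, which(apply(adj[grp, , drop = FALSE], 2, any))))
        if (length(grown) == length(grp)) break
        grp <- grown
      }
      next_id <- next_id + 1L
      comp[idx[grp]] <- next_id
      left <- setdiff(left, grp)
    }
  }
  comp
}

oracle_predictor_matrix <- function(peaks_with_cluster, cluster_targets) {
  ## cluster_targets: named chr vector cluster id -> gene (NA dropped)
  tg <- cluster_targets[!is.na(cluster_targets)]
  genes <- sort(unique(tg))
  tfs <- sort(unique(peaks_with_cluster$tf[
    as.character(peaks_with_cluster$cluster) %in% names(tg)]))
  X <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  for (r in seq_len(nrow(peaks_with_cluster))) {
    cl <- as.character(peaks_with_cluster$cluster[r])
    if (!cl %in% names(tg)) next
    g <- tg[[cl]]
    t <- peaks_with_cluster$tf[r]
    X[g, t] <- max(X[g, t], peaks_with_cluster$norm_signal[r])
  }
  X
}

## pair merge depths by explicit agglomeration over the merge matrix
oracle_pair_depths <- function(tree) {
  labels <- sort(tree$labels)
  n <- length(labels)
  sets <- as.list(tree$labels)          # singleton per leaf, in hclust order
  members <- vector("list", nrow(tree$merge))
  depth <- matrix(n, n, n, dimnames = list(labels, labels))
  for (m in seq_len(nrow(tree$merge))) {
    get <- function(id) if (id < 0) tree$labels[-id] else members[[id]]
    a <- get(tree$merge[m, 1]); b <- get(tree$merge[m, 2])
    members[[m]] <- c(a, b)
    ## pairs first joined at step m stay together for all cuts k <= n - m
    for (x in a) for (y in b) depth[x, y] <- depth[y, x] <- n - m
  }
  pairs <- which(upper.tri(depth), arr.ind = TRUE)
  depth[pairs]
}

oracle_bakers_gamma <- function(t1, t2) {
  cor(oracle_pair_depths(t1), oracle_pair_depths(t2), method = "spearman")
}

oracle_comm_scores <- function(expr, lr_pairs) {
  types <- colnames(expr)
  out <- array(0, c(nrow(lr_pairs), length(types), length(types)))
  for (i in seq_len(nrow(lr_pairs))) for (s in seq_along(types))
    for (r in seq_along(types)) {
      lg <- if (lr_pairs$ligand[i] %in% rownames(expr))
        expr[lr_pairs$ligand[i], s] else 0
      rc <- if (lr_pairs$receptor[i] %in% rownames(expr))
        expr[lr_pairs$receptor[i], r] else 0
      out[i, s, r] <- sqrt(lg * rc)
    }
  out
}

## hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(k, set_size, ess_size, universe_size) {
  sum(vapply(k:min(set_size, ess_size), function(i)
    choose(ess_size, i) * choose(universe_size - ess_size, set_size - i),
    numeric(1))) / choose(universe_size, set_size)
}

## cosine similarity + best factor matching over permutations
cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

match_factors <- function(truth_list, loadings) {
  ## truth_list: per signature, list(lr, sender, receiver) indicator vectors
  r <- length(truth_list)
  perms <- combinat_perms(seq_len(r))
  best <- -Inf; best_perm <- NULL
  for (p in perms) {
    sc <- mean(vapply(seq_len(r), function(i)
      mean(c(cosine(truth_list[[i]]$lr, loadings$lr[, p[i]]),
             cosine(truth_list[[i]]$sender, loadings$sender[, p[i]]),
             cosine(truth_list[[i]]$receiver, loadings$receiver[, p[i]]))),
      numeric(1)))
    if (sc > best) { best <- sc; best_perm <- p }
  }
  best_perm
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
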
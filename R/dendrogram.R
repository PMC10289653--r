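## Dendrogram construction and comparison.

#' Hierarchical clustering of cell types (Ward.D2)
#'
#' Agglomerative clustering of the columns of a feature x cell-type matrix
#' with Euclidean distance and the Ward variance-minimization linkage in its
#' squared-distance ("ward.D2") convention.
#'
#' @param mat numeric feature x cell-type matrix without missing values,
#'   >= 3 columns.
#' @return an [stats::hclust] tree over the cell types.
#' @export
build_dendrogram <- function(mat) {
  if (ncol(mat) < 3) stop("need >= 3 cell types")
  if (anyNA(mat)) stop("input error: NaN/NA in matrix")
  stats::hclust(stats::dist(Matrix::t(mat)), method = "ward.D2")
}

## For every leaf pair, the highest number of clusters k at which the pair is
## still in the same cluster; vector ordered over sorted label pairs.
.pair_depths <- function(tree) {
  labels <- sort(tree$labels)
  n <- length(labels)
  ct <- stats::cutree(tree, k = seq_len(n))     # objects x k
  ct <- ct[labels, , drop = FALSE]
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    max(which(ct[i, ] == ct[j, ]))
  }, numeric(1))
}

#' Baker's gamma correlation between two dendrograms
#'
#' For each pair of leaves, record in each tree the highest number of clusters
#' at which the pair is still merged; Baker's gamma is the Spearman rank
#' correlation of the two pair-depth vectors.
#'
#' @param tree_a,tree_b [stats::hclust] trees over the same leaf set.
#' @return correlation in [-1, 1]; a tree against itself gives 1.
#' @export
bakers_gamma <- function(tree_a, tree_b) {
  if (!setequal(tree_a$labels, tree_b$labels))
    stop("input error: trees have different leaf sets")
  stats::cor(.pair_depths(tree_a), .pair_depths(tree_b), method = "spearman")
}
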
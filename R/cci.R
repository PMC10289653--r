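## Ligand-receptor cell-cell communication scoring.
##
## The communication score of (pair, sender, receiver) is the geometric mean
## of the ligand's pseudobulk expression (mean log1p CPM) in the sender type
## and the receptor's in the receiver type. Significance comes from a
## label-shuffle permutation null (cell-to-cell-type assignments permuted,
## per-type cell counts preserved, the whole aggregation and scoring
## recomputed per permutation) with an add-one p-value estimator. Scores with
## p below alpha form a 3-D communication tensor whose non-negative canonical
## polyadic decomposition yields communication signatures.

#' Communication score for one (pair, sender, receiver) triple
#'
#' @param expr gene x cell-type log1p-CPM matrix (see
#'   [aggregate_log1p_cpm()]).
#' @param ligand,receptor gene ids.
#' @param sender,receiver cell-type ids.
#' @return `sqrt(expr[ligand, sender] * expr[receptor, receiver])`; a gene
#'   missing from `expr` contributes 0 (with a warning).
#' @export
communication_score <- function(expr, ligand, receptor, sender, receiver) {
  lg <- if (ligand %in% rownames(expr)) expr[ligand, sender] else {
    warning("ligand ", ligand, " missing from expression matrix; scored 0"); 0
  }
  rc <- if (receptor %in% rownames(expr)) expr[receptor, receiver] else {
    warning("receptor ", receptor, " missing from expression matrix; scored 0"); 0
  }
  sqrt(lg * rc)
}

## All scores at once: pairs x senders x receivers array.
.score_array <- function(expr, lr_pairs) {
  types <- colnames(expr)
  get_rows <- function(ids) {
    out <- matrix(0, length(ids), length(types),
                  dimnames = list(NULL, types))
    hit <- ids %in% rownames(expr)
    out[hit, ] <- as.matrix(expr[ids[hit], , drop = FALSE])
    out
  }
  L <- get_rows(lr_pairs$ligand)
  R <- get_rows(lr_pairs$receptor)
  n <- nrow(lr_pairs)
  arr <- array(0, dim = c(n, length(types), length(types)),
               dimnames = list(pair = paste(lr_pairs$ligand, lr_pairs$receptor,
                                            sep = "_"),
                               sender = types, receiver = types))
  for (r in seq_along(types))
    arr[, , r] <- sqrt(L * R[, r])
  arr
}

#' Communication scores for all pairs and cell-type combinations
#'
#' @param expr gene x cell-type log1p-CPM matrix.
#' @param lr_pairs data.frame with ligand, receptor (and optionally class)
#'   columns.
#' @return 3-D array pair x sender x receiver. Missing genes score 0 and
#'   trigger one warning listing them.
#' @export
communication_scores <- function(expr, lr_pairs) {
  miss <- setdiff(unique(c(lr_pairs$ligand, lr_pairs$receptor)), rownames(expr))
  if (length(miss))
    warning("genes missing from expression matrix (scored 0): ",
            paste(utils::head(miss, 10), collapse = ", "))
  .score_array(expr, lr_pairs)
}

#' Permutation p-values for communication scores
#'
#' Builds the null by shuffling the cell-to-cell-type labels (preserving the
#' number of cells per type), recomputing the log1p-CPM aggregation and all
#' communication scores for each permutation, and counting null scores at
#' least as large as the observed one: `p = (1 + #{null >= obs}) / (n_perm + 1)`.
#'
#' @param counts gene x cell count matrix.
#' @param labels cell type per cell.
#' @param lr_pairs ligand-receptor pair table.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `scores` (observed array), `p_values` (same shape) and
#'   `n_perm`.
#' @export
permutation_test <- function(counts, labels, lr_pairs, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("configuration error: n_perm must be >= 100")
  labels <- .check_labels(counts, labels)
  E <- log1p_cpm(counts)
  rownames(E) <- rownames(counts)
  G <- .group_mean_matrix(labels)
  types <- colnames(G)
  obs_expr <- as.matrix(E %*% G)
  rownames(obs_expr) <- rownames(counts)
  obs <- .score_array(obs_expr, lr_pairs)

  exceed <- array(0L, dim = dim(obs))
  set.seed(derive_seed(seed, "perm"))
  n_cells <- length(labels)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_cells)
    expr_b <- as.matrix(E %*% G[perm, , drop = FALSE])
    rownames(expr_b) <- rownames(counts)
    null_b <- .score_array(expr_b, lr_pairs)
    exceed <- exceed + (null_b >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  dimnames(p) <- dimnames(obs)
  list(scores = obs, p_values = p, n_perm = as.integer(n_perm))
}

#' Mask communication scores by permutation significance
#'
#' @param scores 3-D score array.
#' @param p_values matching p-value array.
#' @param alpha significance threshold in (0, 1); scores with `p >= alpha`
#'   are set to 0.
#' @param lr_class optional character vector of LR classes (one per pair,
#'   semicolon-separated for multi-class pairs), carried for
#'   [filter_by_class()].
#' @param p_adjust `"none"` (default) thresholds raw permutation p-values;
#'   `"BH"` applies a Benjamini-Hochberg correction across all tensor entries
#'   before thresholding.
#' @return object of class `communication_tensor` with `scores` (masked),
#'   `raw_scores`, `p_values`, `alpha`, `n_retained`.
#' @export
build_tensor <- function(scores, p_values, alpha = 0.05, lr_class = NULL,
                         p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("configuration error: alpha must be in (0, 1]")
  stopifnot(identical(dim(scores), dim(p_values)))
  p_used <- p_values
  if (p_adjust == "BH")
    p_used <- array(stats::p.adjust(p_values, method = "BH"), dim(p_values),
                    dimnames = dimnames(p_values))
  masked <- scores
  masked[p_used >= alpha] <- 0
  structure(list(scores = masked, raw_scores = scores, p_values = p_values,
                 alpha = alpha, n_retained = sum(p_used < alpha),
                 lr_class = lr_class, p_adjust = p_adjust),
            class = "communication_tensor")
}

#' Restrict a communication tensor to LR classes
#'
#' @param tensor a `communication_tensor` whose `lr_class` is set.
#' @param classes classes to keep (any of membrane-bound, ECM, secreted); a
#'   pair is kept when its class annotation intersects `classes`.
#' @return the tensor restricted along the LR mode (possibly with an empty LR
#'   mode).
#' @export
filter_by_class <- function(tensor, classes) {
  stopifnot(inherits(tensor, "communication_tensor"))
  if (is.null(tensor$lr_class)) stop("tensor carries no LR class annotations")
  known <- c("membrane-bound", "ECM", "secreted")
  bad <- setdiff(classes, known)
  if (length(bad)) stop("input error: unknown LR class: ", paste(bad, collapse = ", "))
  ann <- strsplit(tensor$lr_class, ";", fixed = TRUE)
  keep <- vapply(ann, function(a) length(intersect(a, classes)) > 0, logical(1))
  for (f in c("scores", "raw_scores", "p_values"))
    tensor[[f]] <- tensor[[f]][keep, , , drop = FALSE]
  tensor$lr_class <- tensor$lr_class[keep]
  tensor$n_retained <- sum(tensor$p_values < tensor$alpha)
  tensor
}

#' @export
print.communication_tensor <- function(x, ...) {
  d <- dim(x$scores)
  cat(sprintf("Communication tensor: %d LR pairs x %d senders x %d receivers\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %d of %d entries significant at alpha = %g\n",
              x$n_retained, prod(d), x$alpha))
  invisible(x)
}
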
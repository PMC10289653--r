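## Per-cell-type expression profiles.
##
## The scaled-TPM profile of a cell type is computed in five steps: subset the
## size-factor-normalized matrix to the cells of that type, take the per-gene
## mean, divide by the sum of those means, and multiply by one million, so each
## cell-type column sums to 1e6. Bootstrap confidence intervals come from
## resampling cells (with replacement, within the cell type) and recomputing
## the whole profile each time; a gene is called robustly expressed in a cell
## type when the lower bound of its 95% interval is strictly positive.

#' Size-factor normalization
#'
#' Divides each cell by `s_j = total_j / geometric-mean(totals)`, so the
#' geometric mean of the normalized totals equals that of the raw totals.
#'
#' @param counts gene x cell matrix (sparse or dense) of non-negative counts
#'   with gene/cell dimnames.
#' @return a sparse gene x cell matrix of normalized values.
#' @export
size_factor_normalize <- function(counts) {
  .check_counts(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[which(totals <= 0)]
    stop("input error: zero-total cell(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  s <- totals / exp(mean(log(totals)))
  out <- methods::as(counts %*% Matrix::Diagonal(x = 1 / s, names = FALSE), "CsparseMatrix")
  dimnames(out) <- dimnames(counts)
  out
}

.scaled_tpm_from_means <- function(means) {
  sweep(means, 2, colSums(means), "/") * 1e6
}

#' Per-cell-type scaled-TPM point estimates
#'
#' @param norm_matrix output of [size_factor_normalize()].
#' @param labels cell type per cell (named by cell id, or in column order).
#' @return an object of class `cell_type_profile` with `scaled_tpm`
#'   (gene x cell-type matrix whose columns each sum to 1e6) and `n_cells`.
#' @export
aggregate_scaled_tpm <- function(norm_matrix, labels) {
  labels <- .check_labels(norm_matrix, labels)
  G <- .group_mean_matrix(labels)
  means <- as.matrix(norm_matrix %*% G)
  if (any(colSums(means) <= 0))
    stop("input error: a cell type has zero total expression")
  profile <- list(scaled_tpm = .scaled_tpm_from_means(means),
                  ci = list(), robust_mask = NULL,
                  n_cells = table(labels), n_boot = 0L)
  class(profile) <- "cell_type_profile"
  profile
}

#' Bootstrap confidence intervals for cell-type profiles
#'
#' For every cell type with N cells, resamples N of its cells with replacement
#' `n_boot` times, recomputes the scaled-TPM profile each time, and reports
#' percentile confidence intervals at the requested levels. The point estimate
#' is the non-resampled profile.
#'
#' @param counts raw gene x cell count matrix.
#' @param labels cell type per cell.
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param levels confidence levels for the percentile intervals.
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @return a `cell_type_profile` with `ci[[level]]$low` / `$high` matrices,
#'   `robust_mask` (95% lower bound > 0) and `n_boot`.
#' @export
bootstrap_profile <- function(counts, labels, n_boot = 1000, levels = c(0.95, 0.8),
                              seed = 1) {
  if (n_boot < 2) stop("configuration error: n_boot must be >= 2")
  labels <- .check_labels(counts, labels)
  norm <- size_factor_normalize(counts)
  profile <- aggregate_scaled_tpm(norm, labels)
  types <- colnames(profile$scaled_tpm)
  probs <- sort(unique(c((1 - levels) / 2, 1 - (1 - levels) / 2, 0.5)))

  qs <- lapply(types, function(k) {
    j <- which(labels == k)
    N <- length(j)
    set.seed(derive_seed(seed, "bootstrap", k))
    ## resample weights: column b holds multiplicity/N of each cell in draw b
    draws <- sample.int(N, N * n_boot, replace = TRUE)
    W <- vapply(seq_len(n_boot), function(b)
      tabulate(draws[(b - 1L) * N + seq_len(N)], nbins = N) / N,
      numeric(N))
    boots <- as.matrix(norm[, j, drop = FALSE] %*% W)
    tot <- colSums(boots)
    boots <- sweep(boots, 2, tot, "/") * 1e6
    t(apply(boots, 1, quantile, probs = probs, names = FALSE))
  })

  ci <- list()
  for (lv in levels) {
    lo_i <- match((1 - lv) / 2, probs)
    hi_i <- match(1 - (1 - lv) / 2, probs)
    low <- vapply(qs, function(q) q[, lo_i], numeric(nrow(profile$scaled_tpm)))
    high <- vapply(qs, function(q) q[, hi_i], numeric(nrow(profile$scaled_tpm)))
    dimnames(low) <- dimnames(high) <- dimnames(profile$scaled_tpm)
    ci[[sprintf("%g", lv)]] <- list(low = low, high = high)
  }
  med <- vapply(qs, function(q) q[, match(0.5, probs)],
                numeric(nrow(profile$scaled_tpm)))
  dimnames(med) <- dimnames(profile$scaled_tpm)

  profile$ci <- ci
  profile$boot_median <- med
  lv95 <- sprintf("%g", max(levels))
  profile$robust_mask <- ci[[lv95]]$low > 0
  profile$n_boot <- as.integer(n_boot)
  profile
}

#' Percentage of cells expressing each gene, per cell type
#'
#' @inheritParams bootstrap_profile
#' @return gene x cell-type matrix of percentages in [0, 100]; expression
#'   means raw count > 0.
#' @export
percent_expressed <- function(counts, labels) {
  labels <- .check_labels(counts, labels)
  G <- .group_mean_matrix(labels)
  pct <- 100 * as.matrix((counts > 0) %*% G)
  dimnames(pct) <- list(rownames(counts), colnames(G))
  pct
}

#' Mean log1p(CPM) expression per cell type
#'
#' Per cell, counts are scaled to counts-per-million; the per-cell-type value
#' is the mean of `log1p(CPM)` over the cells of the type. This is the
#' pseudobulk representation used for communication scoring.
#'
#' @inheritParams bootstrap_profile
#' @return gene x cell-type matrix.
#' @export
aggregate_log1p_cpm <- function(counts, labels) {
  labels <- .check_labels(counts, labels)
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[which(totals <= 0)]
    stop("input error: zero-total cell(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  E <- log1p_cpm(counts)
  G <- .group_mean_matrix(labels)
  out <- as.matrix(E %*% G)
  dimnames(out) <- list(rownames(counts), colnames(G))
  out
}

## per-cell log1p(CPM), kept sparse (log1p(0) = 0)
log1p_cpm <- function(counts) {
  totals <- Matrix::colSums(counts)
  cpm <- methods::as(counts %*% Matrix::Diagonal(x = 1e6 / totals, names = FALSE),
                     "CsparseMatrix")
  cpm@x <- log1p(cpm@x)
  dimnames(cpm) <- dimnames(counts)
  cpm
}

#' @export
print.cell_type_profile <- function(x, ...) {
  cat("Cell-type expression profile:", nrow(x$scaled_tpm), "genes x",
      ncol(x$scaled_tpm), "cell types\n")
  if (x$n_boot > 0) {
    cat(sprintf("  bootstrap: %d resamples; CI levels: %s\n", x$n_boot,
                paste(names(x$ci), collapse = ", ")))
    cat(sprintf("  robustly expressed genes per type: median %d\n",
                as.integer(stats::median(colSums(x$robust_mask)))))
  }
  invisible(x)
}
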
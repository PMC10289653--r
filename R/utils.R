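## Mixes a base seed with arbitrary scalar tags (numbers or strings) into a
## reproducible stream seed in [1, 2^31 - 2]. Used so that every stage,
## cell type, bootstrap or permutation draws from its own deterministic stream.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  x <- as.double(seed %% m)
  for (tag in list(...)) {
    vals <- if (is.character(tag)) utf8ToInt(paste(tag, collapse = "/")) else as.double(tag)
    for (v in vals) x <- (x * 69069 + v + 1) %% m
  }
  as.integer(max(1, x))
}

## Group indicator matrix: cells x types, column k has 1/n_k on cells of type k
## (so crossprod with an expression matrix yields per-type means).
.group_mean_matrix <- function(labels, types = sort(unique(labels))) {
  G <- matrix(0, length(labels), length(types), dimnames = list(NULL, types))
  for (k in types) {
    idx <- which(labels == k)
    G[idx, k] <- 1 / length(idx)
  }
  G
}

.check_counts <- function(counts) {
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have cell ids as colnames")
  invisible(counts)
}

.check_labels <- function(counts, labels) {
  .check_counts(counts)
  if (is.null(names(labels))) {
    if (length(labels) != ncol(counts)) stop("labels must cover all cells")
    names(labels) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(labels))
  if (length(missing)) {
    stop("labels missing for cells: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  as.character(labels[colnames(counts)])
}

## Area under the ROC curve via the rank-sum (Mann-Whitney) identity;
## ties handled by midranks.
auroc <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("auroc needs both positive and negative labels")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## TSV writers/readers used by all stages so files round-trip exactly.
write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, row_names = NULL) {
  utils::read.table(path, sep = "\t", header = TRUE, row.names = row_names,
                    check.names = FALSE, stringsAsFactors = FALSE, comment.char = "")
}
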
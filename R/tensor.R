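## Non-negative canonical polyadic (CP) decomposition of the communication
## tensor, by hierarchical alternating least squares (HALS): each factor
## column is updated in closed form against the residual and clipped at zero.
## Factors are reported with unit Euclidean norm per mode; the scale of each
## rank-1 component is carried by a weight (lambda), and components are sorted
## by decreasing weight.

.unfold <- function(X, mode) {
  d <- dim(X)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(X, perm), d[mode], prod(d[-mode]))
}

## Khatri-Rao (column-wise Kronecker): rows ordered with B's index fastest,
## matching .unfold's column order for the complementary modes.
.khatri_rao <- function(A, B) {
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- A[, r] %x% B[, r]
  out
}

.nncp_error <- function(X1, A, B, C) {
  recon <- A %*% t(.khatri_rao(C, B))
  sqrt(sum((X1 - recon)^2))
}

.nncp_run <- function(X, rank, init, max_iter = 300, tol = 1e-9) {
  d <- dim(X)
  X1 <- .unfold(X, 1); X2 <- .unfold(X, 2); X3 <- .unfold(X, 3)
  A <- init$A; B <- init$B; C <- init$C
  hals_update <- function(F_, W, V) {
    for (r in seq_len(ncol(F_))) {
      f <- F_[, r] + (W[, r] - F_ %*% V[, r]) / max(V[r, r], 1e-12)
      f <- pmax(f, 0)
      if (sum(f) == 0) f[which.max(W[, r])] <- 1e-12
      F_[, r] <- f
    }
    F_
  }
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    A <- hals_update(A, X1 %*% .khatri_rao(C, B), crossprod(C) * crossprod(B))
    B <- hals_update(B, X2 %*% .khatri_rao(C, A), crossprod(C) * crossprod(A))
    C <- hals_update(C, X3 %*% .khatri_rao(B, A), crossprod(B) * crossprod(A))
    err <- .nncp_error(X1, A, B, C)
    if (is.finite(err_prev) && abs(err_prev - err) <= tol * max(err_prev, 1e-12))
      break
    err_prev <- err
  }
  list(A = A, B = B, C = C, error = err)
}

.random_init <- function(d, rank) {
  list(A = matrix(runif(d[1] * rank, 0.1, 1), d[1], rank),
       B = matrix(runif(d[2] * rank, 0.1, 1), d[2], rank),
       C = matrix(runif(d[3] * rank, 0.1, 1), d[3], rank))
}

#' Non-negative CP decomposition into communication signatures
#'
#' Decomposes the masked communication tensor into `rank` rank-1 non-negative
#' components (signatures), each carrying loading vectors over LR pairs,
#' sender cell types, and receiver cell types. The best of `n_restarts`
#' random restarts (by reconstruction error) is kept; loadings are normalized
#' to unit Euclidean norm per mode with the component scale stored in
#' `weights`, and components are sorted by decreasing weight.
#'
#' @param tensor a `communication_tensor` (or a plain non-negative 3-D
#'   array).
#' @param rank number of signatures (>= 1, at most the smallest tensor
#'   dimension count allows).
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @param init optional warm-start factor list (A, B, C), tried in addition
#'   to the random restarts.
#' @return object of class `cci_signatures` with `loadings` (list `lr`,
#'   `sender`, `receiver`: element x factor matrices), `weights`, `rank`,
#'   `reconstruction_error` (Frobenius) and `relative_error`.
#' @export
decompose <- function(tensor, rank, n_restarts = 5, seed = 1, init = NULL) {
  X <- if (inherits(tensor, "communication_tensor")) tensor$scores else tensor
  stopifnot(length(dim(X)) == 3)
  if (any(X < 0)) stop("tensor must be non-negative")
  if (rank < 1 || rank > min(dim(X)))
    stop("configuration error: rank must be in [1, min tensor dimension]")
  d <- dim(X)
  best <- NULL
  inits <- list()
  if (!is.null(init)) inits <- list(init)
  for (s in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, "nncp", rank, s))
    inits[[length(inits) + 1L]] <- .random_init(d, rank)
  }
  for (ini in inits) {
    run <- .nncp_run(X, rank, ini)
    if (is.null(best) || run$error < best$error) best <- run
  }
  norms <- function(M) apply(M, 2, function(v) sqrt(sum(v^2)))
  na <- pmax(norms(best$A), 1e-12)
  nb <- pmax(norms(best$B), 1e-12)
  nc <- pmax(norms(best$C), 1e-12)
  lambda <- na * nb * nc
  ord <- order(lambda, decreasing = TRUE)
  A <- sweep(best$A, 2, na, "/")[, ord, drop = FALSE]
  B <- sweep(best$B, 2, nb, "/")[, ord, drop = FALSE]
  C <- sweep(best$C, 2, nc, "/")[, ord, drop = FALSE]
  dn <- dimnames(X)
  fac <- paste0("factor", seq_len(rank))
  dimnames(A) <- list(dn[[1]], fac)
  dimnames(B) <- list(dn[[2]], fac)
  dimnames(C) <- list(dn[[3]], fac)
  xnorm <- sqrt(sum(X^2))
  structure(list(loadings = list(lr = A, sender = B, receiver = C),
                 weights = lambda[ord], rank = as.integer(rank),
                 factors_raw = list(A = best$A, B = best$B, C = best$C),
                 reconstruction_error = best$error,
                 relative_error = if (xnorm > 0) best$error / xnorm else 0),
            class = "cci_signatures")
}

#' Reconstruction error versus rank, with an elbow suggestion
#'
#' Runs [decompose()] for each candidate rank in increasing order, warm
#' starting each rank from the previous solution plus one random component
#' (so the error never increases with rank), and suggests the rank at the
#' maximum second difference of the error curve (the elbow).
#'
#' @param tensor a `communication_tensor` or non-negative 3-D array.
#' @param ranks increasing vector of candidate ranks.
#' @param n_restarts random restarts per rank.
#' @param seed integer seed.
#' @return object of class `rank_scan`: data.frame (`rank`, `error`,
#'   `relative_error`) plus `suggested` rank.
#' @export
rank_scan <- function(tensor, ranks = 1:6, n_restarts = 3, seed = 1) {
  if (!length(ranks)) stop("ranks must be non-empty")
  ranks <- sort(unique(as.integer(ranks)))
  X <- if (inherits(tensor, "communication_tensor")) tensor$scores else tensor
  prev <- NULL
  err <- rel <- numeric(length(ranks))
  for (i in seq_along(ranks)) {
    warm <- NULL
    if (!is.null(prev)) {
      extra <- ranks[i] - prev$rank
      if (extra >= 0) {
        set.seed(derive_seed(seed, "warm", ranks[i]))
        pad <- .random_init(dim(X), max(extra, 1))
        warm <- list(A = cbind(prev$factors_raw$A, pad$A[, seq_len(extra), drop = FALSE]),
                     B = cbind(prev$factors_raw$B, pad$B[, seq_len(extra), drop = FALSE]),
                     C = cbind(prev$factors_raw$C, pad$C[, seq_len(extra), drop = FALSE]))
      }
    }
    fit <- decompose(X, ranks[i], n_restarts = n_restarts, seed = seed, init = warm)
    err[i] <- fit$reconstruction_error
    rel[i] <- fit$relative_error
    prev <- fit
  }
  suggested <- ranks[1]
  if (length(ranks) >= 3) {
    d2 <- err[-c(length(err) - 1, length(err))] - 2 * err[-c(1, length(err))] +
      err[-c(1, 2)]
    suggested <- ranks[which.max(d2) + 1L]
  }
  structure(list(table = data.frame(rank = ranks, error = err,
                                    relative_error = rel),
                 suggested = suggested),
            class = "rank_scan")
}

#' @export
print.cci_signatures <- function(x, ...) {
  cat(sprintf("CCI signatures: rank %d, relative reconstruction error %.4f\n",
              x$rank, x$relative_error))
  cat("  component weights:", paste(sprintf("%.3g", x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.rank_scan <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("suggested rank (elbow):", x$suggested, "\n")
  invisible(x)
}
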
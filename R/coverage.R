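## Transcriptome-coverage estimation.
##
## For a cell type with N cells, repeatedly down-sample s < N cells (without
## replacement), recompute the scaled-TPM profile of the subsample, and count
## detected genes (scaled TPM > 0). The mean curve of detected genes vs s is
## fitted with a three-parameter log-logistic function
##     f(x) = d / (1 + exp(b * (log x - log e)))
## whose upper asymptote d is the predicted maximum gene count (G_MAX) and
## whose inflection e is the number of cells needed to detect half of it
## (f(e) = d / 2 exactly). The fraction of the transcriptome covered by the
## observed N cells is f(N) / d.
##
## Because scaled TPM is a positive rescaling of per-gene subsample means, a
## gene has scaled TPM > 0 exactly when it has a nonzero count in the
## subsample; detection is therefore counted directly on the counts.

#' Gene-detection saturation curve for one cell type
#'
#' @param counts gene x cell count matrix.
#' @param labels cell type per cell.
#' @param cell_type cell type to down-sample.
#' @param sizes increasing vector of subsample sizes; default 10 sizes,
#'   geometric from 5 to the number of cells of the type.
#' @param n_iter down-sampling iterations per size.
#' @param seed integer seed; each (cell type, size, iteration) uses its own
#'   derived stream so curves are individually reproducible.
#' @return an object of class `saturation_curve` with `sizes`, `mean_genes`
#'   (mean detected genes over iterations) and `n_iter`.
#' @export
downsample_curve <- function(counts, labels, cell_type, sizes = NULL,
                             n_iter = 100, seed = 1) {
  labels <- .check_labels(counts, labels)
  if (n_iter < 1) stop("n_iter must be >= 1")
  j <- which(labels == cell_type)
  if (!length(j)) stop("input error: unknown cell type ", cell_type)
  N <- length(j)
  if (is.null(sizes)) {
    lo <- min(5, N)
    sizes <- unique(round(exp(seq(log(lo), log(N), length.out = 10))))
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (max(sizes) > N)
    stop("input error: subsample size ", max(sizes), " exceeds the ", N,
         " cells of ", cell_type)
  sub <- counts[, j, drop = FALSE]
  mean_genes <- vapply(seq_along(sizes), function(si) {
    s <- sizes[si]
    det <- vapply(seq_len(n_iter), function(it) {
      set.seed(derive_seed(seed, "downsample", cell_type, s, it))
      pick <- sample.int(N, s)
      sum(Matrix::rowSums(sub[, pick, drop = FALSE]) > 0)
    }, numeric(1))
    mean(det)
  }, numeric(1))
  structure(list(cell_type = cell_type, sizes = sizes, mean_genes = mean_genes,
                 n_iter = as.integer(n_iter)),
            class = "saturation_curve")
}

#' Fit a three-parameter log-logistic saturation model
#'
#' Least-squares fit of `f(x) = d / (1 + exp(b * (log x - log e)))` to a
#' saturation curve, using Levenberg-Marquardt with a grid of starting values
#' (b in {-0.5, -1, -2}; e at the size quartiles; d slightly above the curve
#' maximum) and keeping the best fit by residual sum of squares.
#'
#' @param curve a `saturation_curve`, or a list/data.frame with `sizes` and
#'   `mean_genes`.
#' @return an object of class `log_logistic_fit` with coefficients `b`, `d`
#'   (G_MAX), `e` (cells at half-maximum) and `rss`.
#' @export
fit_log_logistic <- function(curve) {
  x <- as.numeric(curve$sizes)
  y <- as.numeric(curve$mean_genes)
  if (length(unique(x)) < 4) stop("need >= 4 distinct sizes to fit")
  dat <- data.frame(x = x, y = y)
  starts <- expand.grid(b = c(-0.5, -1, -2),
                        e = unname(quantile(x, c(0.25, 0.5, 0.75))),
                        d = max(y) * c(1.05, 1.3))
  best <- NULL
  diagnostics <- character(0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ d / (1 + exp(b * (log(x) - log(e)))), data = dat,
                        start = as.list(starts[i, ]),
                        lower = c(b = -Inf, e = 1e-8, d = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200,
                                                             ftol = 1e-14,
                                                             ptol = 1e-14)),
      error = function(e) { diagnostics <<- c(diagnostics, conditionMessage(e)); NULL })
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("fit error: log-logistic fit failed for all starting values: ",
         paste(unique(diagnostics), collapse = "; "))
  cf <- coef(best$fit)
  structure(list(b = unname(cf["b"]), d = unname(cf["d"]), e = unname(cf["e"]),
                 rss = best$rss, cell_type = curve$cell_type),
            class = "log_logistic_fit")
}

#' Evaluate a fitted log-logistic curve
#' @param object a `log_logistic_fit`.
#' @param newdata optional vector of cell numbers.
#' @param ... unused.
#' @return predicted mean detected genes at `newdata`.
#' @export
predict.log_logistic_fit <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  object$d / (1 + exp(object$b * (log(x) - log(object$e))))
}

#' Coverage summary from a fitted saturation model
#'
#' @param fit a `log_logistic_fit`.
#' @param n_cells_observed number of cells actually sequenced for the type.
#' @return list with `G_MAX` (= d), `cells_for_half` (= e) and
#'   `fraction_covered` = f(n)/d clamped to [0, 1].
#' @export
coverage_report <- function(fit, n_cells_observed) {
  stopifnot(inherits(fit, "log_logistic_fit"))
  if (n_cells_observed <= 0) stop("input error: n_cells_observed must be > 0")
  frac <- predict(fit, n_cells_observed) / fit$d
  list(G_MAX = fit$d, cells_for_half = fit$e,
       fraction_covered = min(1, max(0, frac)))
}

#' Per-cell-type coverage table
#'
#' Runs [downsample_curve()], [fit_log_logistic()] and [coverage_report()] for
#' every cell type and assembles the results.
#'
#' @inheritParams downsample_curve
#' @return data.frame with one row per cell type: n_cells, b, d, e, rss,
#'   fraction_covered.
#' @export
coverage_table <- function(counts, labels, sizes = NULL, n_iter = 100, seed = 1) {
  labels <- .check_labels(counts, labels)
  types <- sort(unique(labels))
  rows <- lapply(types, function(k) {
    curve <- downsample_curve(counts, labels, k, sizes = sizes,
                              n_iter = n_iter, seed = seed)
    fit <- fit_log_logistic(curve)
    rep_ <- coverage_report(fit, sum(labels == k))
    data.frame(cell_type = k, n_cells = sum(labels == k), b = fit$b, d = fit$d,
               e = fit$e, rss = fit$rss,
               fraction_covered = rep_$fraction_covered,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.log_logistic_fit <- function(x, ...) {
  cat(sprintf("Log-logistic saturation fit%s\n",
              if (!is.null(x$cell_type)) paste0(" (", x$cell_type, ")") else ""))
  cat(sprintf("  G_MAX (d) = %.1f genes; half-coverage at e = %.1f cells; b = %.3f; RSS = %.3g\n",
              x$d, x$e, x$b, x$rss))
  invisible(x)
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("Saturation curve for %s: %d sizes (%d-%d cells), %d iterations\n",
              x$cell_type, length(x$sizes), min(x$sizes), max(x$sizes), x$n_iter))
  invisible(x)
}
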
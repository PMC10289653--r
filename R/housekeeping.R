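## Housekeeping-gene scoring.
##
## Two complementary statistics over cell types: the moment skewness (g1) of a
## gene's percent-cells-expressing vector (negative = broadly and abundantly
## expressed) and the Gini coefficient of its scaled-TPM vector (0 = perfectly
## even expression, 1 = maximally concentrated). Genes with Gini below a
## threshold form the outermost ring of a concentric filtration that is then
## intersected with a cross-condition consistent-expression list, an
## essentiality list and a conservation list.

#' Moment skewness of a percent-expressed vector
#'
#' Population moment skewness `g1 = m3 / m2^(3/2)`. Under the sign convention
#' used here a gene expressed in most cells of most cell types (density massed
#' at high percentages) scores negative.
#'
#' @param pct_row numeric vector (one value per cell type), length >= 3.
#' @param type skewness estimator variant (see [e1071::skewness()]); the
#'   default is the plain moment form.
#' @return skewness, or `NA_real_` for a constant vector (undefined).
#' @export
skewness_score <- function(pct_row, type = 1) {
  if (length(pct_row) < 3) stop("need >= 3 cell types to score skewness")
  if (length(unique(pct_row)) == 1L) return(NA_real_)
  e1071::skewness(pct_row, type = type)
}

#' Gini coefficient of an expression vector
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, computed via the equivalent
#' sorted form. 0 for perfectly equal expression, (n-1)/n for a one-hot vector.
#'
#' @param expr_row non-negative numeric vector with positive sum.
#' @return Gini coefficient in [0, 1], or `NA_real_` for an all-zero vector.
#' @export
gini_coefficient <- function(expr_row) {
  if (any(expr_row < 0)) stop("expression values must be non-negative")
  n <- length(expr_row)
  s <- sum(expr_row)
  if (s <= 0) return(NA_real_)
  x <- sort(expr_row)
  (2 * sum(seq_len(n) * x)) / (n * s) - (n + 1) / n
}

#' Classify a Gini coefficient into an expression-equality bracket
#'
#' Brackets: `perfect` (g <= 0.2), `good` (0.2 < g <= 0.3), `adequate`
#' (0.3 < g <= 0.4), `big_gap` (0.4 < g <= 0.5), `severe_gap` (g > 0.5).
#'
#' @param g Gini coefficient(s) in [0, 1]; NA passes through.
#' @return character vector of bracket names.
#' @export
classify_gini <- function(g) {
  ok <- is.na(g) | (g >= 0 & g <= 1)
  if (!all(ok)) stop("input error: Gini coefficient outside [0, 1]")
  cut(g, breaks = c(-Inf, 0.2, 0.3, 0.4, 0.5, Inf),
      labels = c("perfect", "good", "adequate", "big_gap", "severe_gap"),
      right = TRUE) |> as.character()
}

#' Consistency scores for every gene
#'
#' @param scaled_tpm gene x cell-type scaled-TPM matrix (point estimates).
#' @param pct gene x cell-type percent-expressed matrix from
#'   [percent_expressed()].
#' @param skew_type skewness estimator variant, passed to [skewness_score()].
#' @return data.frame (gene, skewness, gini, bracket); genes with zero
#'   expression everywhere get NA scores.
#' @export
gene_consistency_scores <- function(scaled_tpm, pct, skew_type = 1) {
  stopifnot(identical(rownames(scaled_tpm), rownames(pct)))
  gini <- apply(scaled_tpm, 1, gini_coefficient)
  skew <- apply(pct, 1, function(r)
    if (length(unique(r)) == 1L) NA_real_ else skewness_score(r, type = skew_type))
  data.frame(gene = rownames(scaled_tpm), skewness = skew, gini = gini,
             bracket = classify_gini(gini), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Concentric housekeeping-candidate filtration
#'
#' Ring 1 is the set of genes with Gini strictly below `gini_threshold`;
#' each optional list intersects the previous ring, yielding the nested sets
#' consistent-across-types ⊇ consistent-across-conditions ⊇ essential ⊇
#' conserved.
#'
#' @param scores data.frame from [gene_consistency_scores()].
#' @param gini_threshold candidacy threshold (strict inequality).
#' @param cross_condition_list,essential_list,conserved_list optional gene-id
#'   vectors; `NULL` skips the ring.
#' @return object of class `hk_rings`: named list of gene-id vectors plus
#'   `sizes`.
#' @export
housekeeping_candidates <- function(scores, gini_threshold = 0.3,
                                    cross_condition_list = NULL,
                                    essential_list = NULL,
                                    conserved_list = NULL) {
  rings <- list(consistent = scores$gene[!is.na(scores$gini) &
                                           scores$gini < gini_threshold])
  last <- rings$consistent
  for (ring in list(list(name = "cross_condition", set = cross_condition_list),
                    list(name = "essential", set = essential_list),
                    list(name = "conserved", set = conserved_list))) {
    if (is.null(ring$set)) next
    last <- intersect(last, ring$set)
    rings[[ring$name]] <- last
  }
  structure(c(rings, list(sizes = vapply(rings, length, integer(1)),
                          gini_threshold = gini_threshold)),
            class = "hk_rings")
}

#' Fisher enrichment of an annotation within a gene set
#'
#' One-sided (greater) Fisher exact test of the 2x2 table membership x
#' annotation over a gene universe; the p-value equals the hypergeometric
#' upper tail. The odds ratio is the sample cross-product ratio of the table.
#'
#' @param gene_set,essential_set gene-id vectors, subsets of `universe`.
#' @param universe gene-id vector defining the background.
#' @return list with `table` (2x2), `odds_ratio` and `p_value`.
#' @export
essentiality_enrichment <- function(gene_set, essential_set, universe) {
  if (!length(universe)) stop("input error: empty universe")
  gene_set <- intersect(gene_set, universe)
  essential_set <- intersect(essential_set, universe)
  a <- length(intersect(gene_set, essential_set))
  b <- length(gene_set) - a
  c_ <- length(essential_set) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(in_set = c("yes", "no"),
                                essential = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  or <- if (b == 0 || c_ == 0) Inf else (a * d) / (b * c_)
  if (a == 0 && (b == 0 || c_ == 0)) or <- NaN
  list(table = tab, odds_ratio = or, p_value = p)
}

#' @export
print.hk_rings <- function(x, ...) {
  cat("Housekeeping candidate filtration (Gini <", x$gini_threshold, "):\n")
  for (nm in names(x$sizes)) cat(sprintf("  %-16s %d genes\n", nm, x$sizes[[nm]]))
  invisible(x)
}
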
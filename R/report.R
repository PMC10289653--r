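## Human-readable run summary: a text report plus a PDF of diagnostic plots,
## all numbers read back from the stage output files they summarize.

#' Render a summary report for a pipeline run
#'
#' Reads the stage outputs under `run_dir` and writes `report.txt` and
#' `report.pdf` (Gini-bracket histogram, TF-activity heatmap, signature
#' loading heatmaps, coverage table) into `out_dir`. Stages that have not run
#' are reported as missing with a warning rather than an error.
#'
#' @param run_dir pipeline output directory.
#' @param out_dir where to write the report files (default: `run_dir/report`).
#' @return path of the text report, invisibly.
#' @export
render_report <- function(run_dir, out_dir = file.path(run_dir, "report")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con), add = TRUE)
  w <- function(...) writeLines(sprintf(...), con)
  w("wbatlas pipeline report")
  w("=======================")

  pdf_path <- file.path(out_dir, "report.pdf")
  grDevices::pdf(pdf_path, width = 7, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)

  f <- file.path(run_dir, "housekeeping", "hk_scores.tsv")
  if (file.exists(f)) {
    scores <- read_tsv(f)
    tab <- table(factor(scores$bracket,
                        levels = c("perfect", "good", "adequate", "big_gap",
                                   "severe_gap")))
    w("")
    w("Gini brackets (genes per expression-equality class):")
    for (nm in names(tab)) w("  %-10s %d", nm, tab[[nm]])
    graphics::barplot(tab, main = "Expression-equality brackets",
                      ylab = "genes", las = 2)
  } else warning("housekeeping outputs missing; partial report")

  f <- file.path(run_dir, "coverage", "coverage.tsv")
  if (file.exists(f)) {
    cov <- read_tsv(f)
    w("")
    w("Transcriptome coverage per cell type:")
    w("  %-8s %8s %10s %10s %10s", "type", "n_cells", "G_MAX", "half_at",
      "fraction")
    for (i in seq_len(nrow(cov)))
      w("  %-8s %8d %10.1f %10.1f %10.3f", cov$cell_type[i], cov$n_cells[i],
        cov$d[i], cov$e[i], cov$fraction_covered[i])
  } else warning("coverage outputs missing; partial report")

  f <- file.path(run_dir, "tfactivity", "tf_activity.tsv")
  if (file.exists(f)) {
    act <- read_tsv(f)
    B <- tapply(act$beta_clipped, list(act$tf, act$cell_type), mean)
    w("")
    w("TF activity: %d TFs x %d cell types; %d positive associations",
      nrow(B), ncol(B), sum(B > 0, na.rm = TRUE))
    graphics::image(t(B), main = "TF activity (clipped coefficients)",
                    xlab = "cell types", ylab = "TFs", axes = FALSE)
    g <- file.path(run_dir, "tfactivity", "gamma.json")
    if (file.exists(g)) {
      gm <- jsonlite::read_json(g)
      w("Baker's gamma: activity vs all-gene tree %.3f; TF expression vs all-gene tree %.3f",
        gm$activity_vs_all_genes, gm$tf_expression_vs_all_genes)
    }
  } else warning("tfactivity outputs missing; partial report")

  f <- file.path(run_dir, "cci", "signatures")
  if (dir.exists(f)) {
    for (mode in c("sender", "receiver", "lr")) {
      L <- as.matrix(read_tsv(file.path(f, sprintf("loadings_%s.tsv", mode)),
                              row_names = 1))
      graphics::image(t(L), main = sprintf("Signature loadings: %s mode", mode),
                      xlab = "factors", ylab = mode, axes = FALSE)
    }
    err <- jsonlite::read_json(file.path(f, "error.json"))
    w("")
    w("CCI signatures: rank %d, relative reconstruction error %.4f, %d significant tensor entries",
      err$rank, err$relative_error, err$n_retained)
  } else warning("cci outputs missing; partial report")

  invisible(txt)
}
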
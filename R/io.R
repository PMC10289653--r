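## Plain-text dataset I/O. All stages read and write the same formats:
## Matrix Market counts + genes.tsv/cells.tsv, TSV metadata tables and a JSON
## ground-truth record, so a simulated dataset round-trips losslessly.

#' Write a synthetic atlas (or any compatible dataset) to a directory
#'
#' Emits `matrix.mtx`, `genes.tsv`, `cells.tsv`, `labels.tsv`,
#' `tss.tsv`, `peaks.tsv`, `lr_pairs.tsv`, `truth.json` and `config.json`.
#'
#' @param atlas a `synthetic_atlas` (or a list with the same fields).
#' @param dir output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(atlas, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("I/O error: cannot create directory ", dir)
  Matrix::writeMM(atlas$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(atlas$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(atlas$counts), file.path(dir, "cells.tsv"))
  write_tsv(data.frame(cell_id = names(atlas$cell_labels),
                       cell_type = unname(atlas$cell_labels)),
            file.path(dir, "labels.tsv"))
  if (!is.null(atlas$gene_annotation))
    write_tsv(atlas$gene_annotation[, c("gene", "chrom", "tss", "strand")],
              file.path(dir, "tss.tsv"))
  if (!is.null(atlas$peaks))
    write_tsv(atlas$peaks[, c("chrom", "apex", "tf", "stage", "signal")],
              file.path(dir, "peaks.tsv"))
  if (!is.null(atlas$lr_pairs))
    write_tsv(atlas$lr_pairs[, c("ligand", "receptor", "class")],
              file.path(dir, "lr_pairs.tsv"))
  if (!is.null(atlas$truth)) {
    tr <- atlas$truth
    out <- list(
      housekeeping_genes = tr$housekeeping_genes,
      marker_genes = list(gene = unname(tr$marker_genes),
                          cell_type = names(tr$marker_genes)),
      tf_activity_weights = list(tf = rownames(tr$tf_activity_weights),
                                 cell_type = colnames(tr$tf_activity_weights),
                                 weights = tr$tf_activity_weights),
      tf_targets = tr$tf_targets,
      tf_target_signal = list(gene = rownames(tr$tf_target_signal),
                              tf = colnames(tr$tf_target_signal),
                              signal = tr$tf_target_signal),
      lr_signatures = tr$lr_signatures,
      decoy_hot_regions = tr$decoy_hot_regions,
      singleton_peaks = tr$singleton_peaks,
      group_of = as.list(tr$group_of)
    )
    jsonlite::write_json(out, file.path(dir, "truth.json"), digits = NA)
  }
  if (!is.null(atlas$config))
    jsonlite::write_json(unclass(atlas$config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the files.
#' @return a `synthetic_atlas`-shaped list (without generator internals).
#' @export
read_dataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "cells.tsv"))
  lab <- read_tsv(file.path(dir, "labels.tsv"))
  labels <- setNames(as.character(lab$cell_type), lab$cell_id)

  annotation <- peaks <- lr <- truth <- config <- NULL
  f <- file.path(dir, "tss.tsv"); if (file.exists(f)) annotation <- read_tsv(f)
  f <- file.path(dir, "peaks.tsv"); if (file.exists(f)) peaks <- read_tsv(f)
  f <- file.path(dir, "lr_pairs.tsv"); if (file.exists(f)) lr <- read_tsv(f)
  f <- file.path(dir, "config.json")
  if (file.exists(f)) {
    config <- jsonlite::read_json(f, simplifyVector = TRUE)
    class(config) <- "sim_config"
  }
  f <- file.path(dir, "truth.json")
  if (file.exists(f)) {
    raw <- jsonlite::read_json(f, simplifyVector = TRUE)
    W <- as.matrix(raw$tf_activity_weights$weights)
    dimnames(W) <- list(raw$tf_activity_weights$tf, raw$tf_activity_weights$cell_type)
    S <- as.matrix(raw$tf_target_signal$signal)
    dimnames(S) <- list(raw$tf_target_signal$gene, raw$tf_target_signal$tf)
    sigs <- raw$lr_signatures
    if (is.data.frame(sigs)) {
      sigs <- lapply(seq_len(nrow(sigs)), function(i)
        list(senders = unlist(sigs$senders[i]), receivers = unlist(sigs$receivers[i]),
             pairs = unlist(sigs$pairs[i])))
    } else if (is.null(sigs)) sigs <- list()
    truth <- list(
      housekeeping_genes = as.character(unlist(raw$housekeeping_genes)),
      marker_genes = setNames(as.character(unlist(raw$marker_genes$gene)),
                              as.character(unlist(raw$marker_genes$cell_type))),
      tf_activity_weights = W,
      tf_targets = lapply(raw$tf_targets, function(x) as.character(unlist(x))),
      tf_target_signal = S,
      lr_signatures = sigs,
      decoy_hot_regions = as.data.frame(raw$decoy_hot_regions),
      singleton_peaks = as.character(unlist(raw$singleton_peaks)),
      group_of = unlist(raw$group_of)
    )
    class(truth) <- "synthetic_truth"
  }
  atlas <- list(counts = counts, cell_labels = labels, gene_annotation = annotation,
                peaks = peaks, lr_pairs = lr, truth = truth, config = config,
                internal = NULL)
  class(atlas) <- "synthetic_atlas"
  atlas
}
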
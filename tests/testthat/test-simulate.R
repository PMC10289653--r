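test_that("generator respects configuration invariants and determinism", {
  expect_error(sim_config(n_genes = 100), "configuration error")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(n_signatures = 99, n_lr_pairs = 60, n_genes = 4000),
               "n_signatures")

  cfg <- sim_config(n_cell_types = 4, cells_per_type = 30, n_genes = 300,
                    n_housekeeping = 0, n_markers_per_type = 5, n_tfs = 6,
                    targets_per_tf = 4, n_lr_pairs = 10, n_signatures = 2,
                    n_groups = 2, seed = 7)
  a1 <- simulate_atlas(cfg)
  a2 <- simulate_atlas(cfg)
  expect_identical(a1$truth$housekeeping_genes, character(0))
  expect_identical(as.matrix(a1$counts), as.matrix(a2$counts))
  expect_identical(a1$peaks, a2$peaks)
  expect_identical(a1$lr_pairs, a2$lr_pairs)
  expect_equal(length(unique(a1$cell_labels)), 4)
  expect_true(all(Matrix::colSums(a1$counts) > 0))
  expect_true(all(a1$lr_pairs$class %in% c("membrane-bound", "ECM", "secreted")))
  ## every TF with weights appears in the target map; signature pairs exist
  expect_true(all(rownames(a1$truth$tf_activity_weights) %in%
                    names(a1$truth$tf_targets)))
  all_pairs <- paste(a1$lr_pairs$ligand, a1$lr_pairs$receptor, sep = "_")
  for (s in a1$truth$lr_signatures) expect_true(all(s$pairs %in% all_pairs))
})

test_that("housekeeping means are flat across cell types under the model", {
  a <- default_atlas()
  norm <- size_factor_normalize(a$counts)
  hk <- a$truth$housekeeping_genes
  types <- sort(unique(a$cell_labels))
  ## per gene, per type: mean and standard error of normalized expression;
  ## flatness: type mean within 3 SE of the gene's grand mean
  ok <- vapply(hk, function(g) {
    x <- norm[g, ]
    grand <- mean(x)
    close <- vapply(types, function(k) {
      v <- x[a$cell_labels == k]
      se <- stats::sd(v) / sqrt(length(v))
      abs(mean(v) - grand) < 3 * se
    }, logical(1))
    mean(close)
  }, numeric(1))
  expect_gte(mean(ok), 0.95)
})

test_that("planted peaks pass the assignment rules and decoys are flagged", {
  cfg <- sim_config(seed = 3)
  a <- simulate_peaks(simulate_counts(cfg))
  pc <- assign_targets(filter_clusters(cluster_peaks(a$peaks)),
                       a$gene_annotation)
  assigned <- pc$clusters$target_gene
  ## noise-free placement: every planted (tf, target) is recovered exactly
  planted <- sort(unique(unlist(a$truth$tf_targets)))
  expect_setequal(sort(assigned[!is.na(assigned)]), planted)
  ## decoy HOT regions form clusters of > 70 distinct TFs before filtering
  raw <- cluster_peaks(a$peaks)
  for (i in seq_len(nrow(a$truth$decoy_hot_regions))) {
    reg <- a$truth$decoy_hot_regions[i, ]
    hit <- raw$clusters$chrom == reg$chrom &
      raw$clusters$mean_apex >= reg$start & raw$clusters$mean_apex <= reg$end
    expect_true(any(raw$clusters$n_tfs[hit] > 70))
  }
  ## with no decoys or singletons every cluster survives the filter
  a2 <- simulate_peaks(simulate_counts(
    sim_config(seed = 4, n_decoy_hot = 0, n_singletons = 0)))
  raw2 <- cluster_peaks(a2$peaks)
  kept2 <- filter_clusters(raw2)
  expect_equal(nrow(kept2$clusters), nrow(raw2$clusters))
})

test_that("stronger TF activity raises planted target expression monotonically", {
  means <- vapply(c(1, 3, 9), function(sc) {
    a <- simulate_counts(sim_config(n_cell_types = 4, cells_per_type = 40,
                                    n_genes = 400, n_housekeeping = 10,
                                    n_markers_per_type = 5, n_tfs = 6,
                                    targets_per_tf = 4, n_lr_pairs = 10,
                                    n_groups = 2, tf_activity_scale = sc,
                                    seed = 9))
    W <- a$truth$tf_activity_weights
    tot <- 0; n <- 0
    for (tf in rownames(W)) {
      active <- colnames(W)[W[tf, ] > 0]
      tg <- a$truth$tf_targets[[tf]]
      cells <- a$cell_labels %in% active
      tot <- tot + sum(a$counts[tg, cells]); n <- n + length(tg) * sum(cells)
    }
    tot / n
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("per-cell totals follow the configured log-normal library model", {
  a <- simulate_counts(sim_config(n_cell_types = 10, cells_per_type = 200,
                                  n_genes = 1200, n_housekeeping = 80,
                                  n_markers_per_type = 10, n_tfs = 20,
                                  targets_per_tf = 10, n_lr_pairs = 30,
                                  seed = 21))
  lt <- log(Matrix::colSums(a$counts))
  ## discrete totals occasionally tie; the KS statistic itself is unaffected
  p <- suppressWarnings(stats::ks.test(lt, "pnorm", mean(lt), stats::sd(lt)))$p.value
  expect_gt(p, 0.01)
})

test_that("datasets round-trip losslessly through write_dataset/read_dataset", {
  cfg <- sim_config(n_cell_types = 3, cells_per_type = 20, n_genes = 250,
                    n_housekeeping = 10, n_markers_per_type = 4, n_tfs = 6,
                    targets_per_tf = 4, n_lr_pairs = 8, n_signatures = 1,
                    n_groups = 3, seed = 5)
  a <- simulate_atlas(cfg)
  dir <- withr::local_tempdir()
  write_dataset(a, dir)
  expect_identical(readLines(file.path(dir, "peaks.tsv"), n = 1),
                   "chrom\tapex\ttf\tstage\tsignal")
  b <- read_dataset(dir)
  expect_equal(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cell_labels, b$cell_labels)
  expect_equal(a$peaks, b$peaks)
  expect_equal(a$lr_pairs, b$lr_pairs)
  expect_identical(a$truth$housekeeping_genes, b$truth$housekeeping_genes)
  expect_equal(a$truth$tf_activity_weights, b$truth$tf_activity_weights)
  expect_identical(lapply(a$truth$tf_targets, sort),
                   lapply(b$truth$tf_targets, sort))
  expect_identical(a$truth$singleton_peaks, b$truth$singleton_peaks)
  expect_equal(length(a$truth$lr_signatures), length(b$truth$lr_signatures))
  for (i in seq_along(a$truth$lr_signatures)) {
    expect_setequal(a$truth$lr_signatures[[i]]$senders,
                    b$truth$lr_signatures[[i]]$senders)
    expect_setequal(a$truth$lr_signatures[[i]]$pairs,
                    b$truth$lr_signatures[[i]]$pairs)
  }
  ## writing the same dataset twice produces byte-identical files
  dir2 <- withr::local_tempdir()
  write_dataset(a, dir2)
  f1 <- sort(list.files(dir, full.names = TRUE))
  f2 <- sort(list.files(dir2, full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
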
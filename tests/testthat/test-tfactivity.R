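test_that("peak clustering applies the gap rule and partitions the peaks", {
  p <- data.frame(chrom = "chrI", apex = c(100, 250, 460), tf = c("a", "b", "a"),
                  stage = "YA", signal = 1)
  pc <- cluster_peaks(p)
  expect_equal(nrow(pc$clusters), 2)
  expect_equal(sort(pc$clusters$n_peaks), c(1, 2))
  expect_equal(pc$clusters$mean_apex[1], 175)       # {100, 250}: gap 150 merges
  ## exactly one peak: a singleton cluster
  expect_equal(nrow(cluster_peaks(p[1, ])$clusters), 1)
  ## boundary: gap of exactly 200 starts a new cluster
  p2 <- data.frame(chrom = "chrI", apex = c(0, 199, 399), tf = "a",
                   stage = "YA", signal = 1)
  expect_equal(nrow(cluster_peaks(p2)$clusters), 2)
  expect_error(cluster_peaks(data.frame(chrom = "chrI", apex = -5, tf = "a")),
               "negative apex")
  ## 500 random peaks on 3 chromosomes vs gap-graph connected components
  set.seed(4)
  pr <- data.frame(chrom = sample(c("chrI", "chrII", "chrIII"), 500, TRUE),
                   apex = sample.int(50000, 500), tf = sample(letters[1:9], 500, TRUE),
                   stage = "YA", signal = runif(500, 1, 9))
  pc2 <- cluster_peaks(pr)
  expect_equal(nrow(pc2$peaks), nrow(pr))           # a partition: no peak lost
  oracle <- oracle_cluster(pc2$peaks)
  ## same partition up to relabeling
  expect_equal(length(unique(oracle)), nrow(pc2$clusters))
  expect_true(all(tapply(oracle, pc2$peaks$cluster,
                         function(v) length(unique(v))) == 1))
})

test_that("HOT and single-TF clusters are filtered at the documented bounds", {
  mk <- function(n_tfs, base) data.frame(chrom = "chrI",
                                         apex = base + seq_len(n_tfs) * 2,
                                         tf = sprintf("tf%03d", seq_len(n_tfs)),
                                         stage = "YA", signal = 1)
  peaks <- rbind(mk(71, 0), mk(70, 10000), mk(2, 20000), mk(1, 30000))
  pc <- filter_clusters(cluster_peaks(peaks))
  expect_equal(sort(pc$clusters$n_tfs), c(2, 70))   # 71 removed, 70 kept
  expect_equal(unname(attr(pc, "removed")), c(1, 1))
  ## synthetic decoys and singletons are exactly the removals
  a <- simulate_peaks(simulate_counts(sim_config(seed = 6)))
  raw <- cluster_peaks(a$peaks)
  kept <- filter_clusters(raw)
  removed_ids <- setdiff(raw$clusters$cluster, kept$clusters$cluster)
  removed <- raw$clusters[raw$clusters$cluster %in% removed_ids, ]
  ## every planted singleton is removed
  single_keys <- paste0(removed$chrom[removed$n_tfs == 1], ":",
                        removed$mean_apex[removed$n_tfs == 1])
  expect_setequal(single_keys, a$truth$singleton_peaks)
  ## every decoy HOT region is removed
  expect_equal(sum(removed$n_tfs > 70), nrow(a$truth$decoy_hot_regions))
})

test_that("target assignment honors the distance and ambiguity rules", {
  tss <- data.frame(gene = c("gA", "gB"), chrom = "chrI", tss = c(10000, 16000))
  clu <- function(apex) {
    pc <- cluster_peaks(data.frame(chrom = "chrI", apex = apex,
                                   tf = c("x", "y"), stage = "YA", signal = 1))
    assign_targets(pc, tss)$clusters$target_gene
  }
  expect_equal(clu(c(10999, 11001)), "gA")     # d1 = 1000, d2 = 5000: assigned
  ## ambiguity rule: d1 = 1500, d2 = 2000 < 1.5 * 1500 stays unassigned
  tss2 <- data.frame(gene = c("gA", "gB"), chrom = "chrI", tss = c(10000, 13500))
  pc2 <- cluster_peaks(data.frame(chrom = "chrI", apex = c(11499, 11501),
                                  tf = c("x", "y"), stage = "YA", signal = 1))
  expect_true(is.na(assign_targets(pc2, tss2)$clusters$target_gene))
  ## distance rule: d1 = 2500 unassigned even when unambiguous
  tss3 <- data.frame(gene = c("gA", "gB"), chrom = "chrI", tss = c(10000, 21500))
  pc3 <- cluster_peaks(data.frame(chrom = "chrI", apex = c(12499, 12501),
                                  tf = c("x", "y"), stage = "YA", signal = 1))
  expect_true(is.na(assign_targets(pc3, tss3)$clusters$target_gene))
  ## apex exactly on a TSS: assigned regardless of the ratio
  pc4 <- cluster_peaks(data.frame(chrom = "chrI", apex = c(10000, 10000),
                                  tf = c("x", "y"), stage = "YA", signal = 1))
  tss4 <- data.frame(gene = c("gA", "gB"), chrom = "chrI", tss = c(10000, 10001))
  expect_equal(assign_targets(pc4, tss4)$clusters$target_gene, "gA")
  ## exact d1 = d2 tie stays unassigned
  tss5 <- data.frame(gene = c("gA", "gB"), chrom = "chrI", tss = c(9000, 11000))
  pc5 <- cluster_peaks(data.frame(chrom = "chrI", apex = c(9999, 10001),
                                  tf = c("x", "y"), stage = "YA", signal = 1))
  expect_true(is.na(assign_targets(pc5, tss5)$clusters$target_gene))
  ## joint translation of apexes and TSSs leaves assignments unchanged
  a <- simulate_peaks(simulate_counts(sim_config(seed = 8)))
  pc <- assign_targets(filter_clusters(cluster_peaks(a$peaks)),
                       a$gene_annotation)
  shifted_peaks <- a$peaks; shifted_peaks$apex <- shifted_peaks$apex + 5000
  shifted_tss <- a$gene_annotation; shifted_tss$tss <- shifted_tss$tss + 5000
  pcs <- assign_targets(filter_clusters(cluster_peaks(shifted_peaks)),
                        shifted_tss)
  expect_identical(pc$clusters$target_gene, pcs$clusters$target_gene)
})

test_that("signal rank normalization and predictor aggregation match oracles", {
  p <- data.frame(chrom = "chrI", apex = 1:3, tf = "a", stage = "YA",
                  signal = c(3, 7, 9))
  expect_equal(normalize_signals(p)$norm_signal, c(1, 2, 3) / 3)
  p2 <- data.frame(chrom = "chrI", apex = 1:2, tf = "a", stage = "YA",
                   signal = c(5, 5))
  expect_equal(normalize_signals(p2)$norm_signal, c(0.75, 0.75))
  ## mixed experiments: each (tf, stage) group normalized on its own
  set.seed(6)
  p3 <- data.frame(chrom = "chrI", apex = seq(1, 4000, 20),
                   tf = sample(c("a", "b"), 200, TRUE),
                   stage = sample(c("YA", "EM"), 200, TRUE),
                   signal = runif(200, 0.1, 50))
  n3 <- normalize_signals(p3)
  for (tf in c("a", "b")) for (st in c("YA", "EM")) {
    idx <- which(p3$tf == tf & p3$stage == st)
    expect_equal(n3$norm_signal[idx], rank(p3$signal[idx]) / length(idx))
    expect_equal(max(n3$norm_signal[idx]), 1)
  }
  ## predictor matrix: max aggregation over peaks and clusters
  peaks <- data.frame(chrom = "chrI",
                      apex = c(1000, 1001, 1002, 9000, 9001, 30000),
                      tf = c("A", "A", "B", "A", "B", "B"), stage = "YA",
                      signal = c(2, 8, 5, 9, 1, 4))
  pc <- cluster_peaks(normalize_signals(peaks))
  pc$clusters$target_gene <- c("g1", "g1", "g2")
  X <- build_predictor_matrix(pc)
  tgt <- setNames(pc$clusters$target_gene, pc$clusters$cluster)
  expect_equal(X, oracle_predictor_matrix(pc$peaks, tgt))
  ## duplicating a peak never changes X (max is idempotent)
  pc_dup <- cluster_peaks(normalize_signals(rbind(peaks, peaks[2, ])))
  pc_dup$clusters$target_gene <- c("g1", "g1", "g2")
  expect_equal(build_predictor_matrix(pc_dup), X)
})

test_that("lasso recovers planted regulators against decoy TFs", {
  set.seed(9)
  n_genes <- 220; n_tf <- 31
  X <- matrix(runif(n_genes * n_tf), n_genes, n_tf,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("tf%02d", 1:n_tf)))
  X[X < 0.6] <- 0                                  # sparse binding
  y_signal <- 2 * X[, "tf01"] + rnorm(n_genes, 0, 0.05)
  stpm <- cbind(t1 = expm1(pmax(y_signal, 0)),     # log1p(y) recovers the signal
                t2 = expm1(rep(0.5, n_genes)))     # constant response
  prof <- structure(list(scaled_tpm = stpm, robust_mask = NULL,
                         n_cells = c(t1 = 10, t2 = 10), n_boot = 0L),
                    class = "cell_type_profile")
  fit <- fit_tf_models(X, prof, folds = 10, seed = 1)
  expect_gt(fit$beta["tf01", "t1"], 0)
  expect_equal(names(which.max(fit$beta[, "t1"])), "tf01")
  expect_lte(fit$cv_mse[["t1"]], stats::var(log1p(stpm[, "t1"])))
  ## constant response: intercept-only fit, all clipped coefficients zero
  expect_true(all(fit$beta[, "t2"] == 0))
  expect_true(all(fit$beta >= 0))
  ## deterministic given the seed
  fit2 <- fit_tf_models(X, prof, folds = 10, seed = 1)
  expect_identical(fit$beta, fit2$beta)
  expect_error(fit_tf_models(X[1:5, ], prof, folds = 10), "folds")
})

test_that("noise-free single-regulator cell types are identified by argmax", {
  set.seed(12)
  K <- 8; n_tf <- 20; n_genes <- 160
  X <- matrix(0, n_genes, n_tf, dimnames = list(sprintf("g%03d", 1:n_genes),
                                                sprintf("tf%02d", 1:n_tf)))
  for (t in seq_len(n_tf)) X[sample.int(n_genes, 25), t] <- runif(25, 0.5, 1)
  active <- sample.int(n_tf, K)
  stpm <- sapply(seq_len(K), function(k) expm1(3 * X[, active[k]]))
  colnames(stpm) <- sprintf("t%02d", seq_len(K))
  prof <- structure(list(scaled_tpm = stpm, robust_mask = NULL,
                         n_cells = setNames(rep(10, K), colnames(stpm)),
                         n_boot = 0L), class = "cell_type_profile")
  fit <- fit_tf_models(X, prof, folds = 10, seed = 2)
  hits <- vapply(seq_len(K), function(k)
    names(which.max(fit$beta[, k])) == sprintf("tf%02d", active[k]), logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("embryonic-stage peaks defer to post-embryonic experiments", {
  p <- data.frame(chrom = "chrI", apex = 1:4,
                  tf = c("a", "a", "b", "c"),
                  stage = c("EM", "YA", "EM", "YA"), signal = 1)
  kept <- filter_stage_precedence(p)
  expect_setequal(paste(kept$tf, kept$stage), c("a YA", "b EM", "c YA"))
})
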
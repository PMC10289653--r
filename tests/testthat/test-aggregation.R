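test_that("size factors follow the geometric-mean convention", {
  ## equal totals: matrix unchanged
  m <- Matrix::Matrix(matrix(c(2, 3, 5, 4, 1, 5), 3,
                             dimnames = list(paste0("g", 1:3), c("a", "b"))),
                      sparse = TRUE)
  expect_equal(as.matrix(size_factor_normalize(m)), as.matrix(m))
  ## totals 10 and 1000: s = (0.1, 10)
  m2 <- Matrix::Matrix(matrix(c(10, 0, 0, 1000), 2,
                              dimnames = list(c("g1", "g2"), c("a", "b"))),
                       sparse = TRUE)
  norm <- size_factor_normalize(m2)
  expect_equal(norm[1, "a"], 100)
  expect_equal(norm[2, "b"], 100)
  ## random matrix equals brute-force per-cell division
  fx <- tiny_counts(5, 6, 2, seed = 1)
  s <- colSums(fx$dense) / exp(mean(log(colSums(fx$dense))))
  expect_equal(as.matrix(size_factor_normalize(fx$counts)),
               sweep(fx$dense, 2, s, "/"))
  ## zero-total cell is an error naming the cell
  m3 <- fx$counts
  m3[, 3] <- 0
  expect_error(size_factor_normalize(m3), "c03")
})

test_that("scaled TPM matches the stepwise definition and sums to 1e6", {
  ## single type, one nonzero gene
  m <- Matrix::Matrix(matrix(c(0, 4, 0, 0, 2, 0), 3,
                             dimnames = list(paste0("g", 1:3), c("a", "b"))),
                      sparse = TRUE)
  p <- aggregate_scaled_tpm(size_factor_normalize(m),
                            setNames(c("t", "t"), c("a", "b")))
  expect_equal(unname(p$scaled_tpm[, "t"]), c(0, 1e6, 0))
  ## toy two-type example against the hand oracle
  fx <- tiny_counts(3, 4, 2, seed = 3)
  norm <- as.matrix(size_factor_normalize(fx$counts))
  p2 <- aggregate_scaled_tpm(size_factor_normalize(fx$counts), fx$labels)
  expect_equal(p2$scaled_tpm, oracle_scaled_tpm(norm, fx$labels))
  ## random larger case: column sums and cell-permutation invariance
  fx3 <- tiny_counts(40, 60, 4, seed = 8)
  p3 <- aggregate_scaled_tpm(size_factor_normalize(fx3$counts), fx3$labels)
  expect_equal(unname(colSums(p3$scaled_tpm)), rep(1e6, 4), tolerance = 1e-9)
  perm <- sample(ncol(fx3$counts))
  p3p <- aggregate_scaled_tpm(size_factor_normalize(fx3$counts[, perm]),
                              fx3$labels[perm])
  expect_equal(p3$scaled_tpm, p3p$scaled_tpm)
  expect_error(aggregate_scaled_tpm(size_factor_normalize(fx3$counts),
                                    fx3$labels[-1]), "labels")
})

test_that("percent expressed and log1p-CPM pseudobulk match brute force", {
  fx <- tiny_counts(6, 8, 2, seed = 5, lambda = 1.5)
  expect_equal(percent_expressed(fx$counts, fx$labels),
               oracle_percent_expressed(fx$dense, fx$labels))
  expect_equal(aggregate_log1p_cpm(fx$counts, fx$labels),
               oracle_log1p_cpm(fx$dense, fx$labels))
  ## closed forms
  one <- Matrix::Matrix(matrix(c(7), 1, dimnames = list("g1", "c1")), sparse = TRUE)
  lab1 <- setNames("t", "c1")
  expect_equal(unname(aggregate_log1p_cpm(one, lab1)[1, 1]), log1p(1e6))
  expect_equal(unname(percent_expressed(one, lab1)[1, 1]), 100)
  quarter <- Matrix::Matrix(matrix(c(1, 0, 0, 0, 5, 5, 5, 5), 2, byrow = TRUE,
                                   dimnames = list(c("g1", "g2"), paste0("c", 1:4))),
                            sparse = TRUE)
  expect_equal(unname(percent_expressed(quarter,
                                        setNames(rep("t", 4), paste0("c", 1:4)))[1, 1]),
               25)
})

test_that("bootstrap intervals behave at the deterministic extremes", {
  set.seed(10)
  n <- 40
  m <- rbind(g1 = rep(0, n),                      # silent gene
             g2 = rpois(n, 4) + 1,                # expressed in every cell
             g3 = rbinom(n, 1, 0.5) * rpois(n, 5),
             g4 = rpois(n, 2))
  colnames(m) <- sprintf("c%02d", 1:n)
  cm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  labels <- setNames(rep("t", n), colnames(m))
  prof <- bootstrap_profile(cm, labels, n_boot = 400, seed = 2)
  expect_equal(unname(prof$ci[["0.95"]]$low["g1", ]), 0)
  expect_equal(unname(prof$ci[["0.95"]]$high["g1", ]), 0)
  expect_false(prof$robust_mask["g1", ])
  expect_true(prof$robust_mask["g2", ])
  expect_gt(prof$ci[["0.95"]]$low["g2", ], 0)
  ## interval nesting and median containment
  expect_true(all(prof$ci[["0.95"]]$low <= prof$ci[["0.8"]]$low))
  expect_true(all(prof$ci[["0.8"]]$high <= prof$ci[["0.95"]]$high))
  expect_true(all(prof$ci[["0.95"]]$low <= prof$boot_median + 1e-9))
  expect_true(all(prof$boot_median <= prof$ci[["0.95"]]$high + 1e-9))
  ## bit-reproducible given the seed
  prof2 <- bootstrap_profile(cm, labels, n_boot = 400, seed = 2)
  expect_identical(prof$ci, prof2$ci)
  expect_error(bootstrap_profile(cm, labels, n_boot = 1), "n_boot")
})

test_that("robust calls imply detection and CI endpoints stabilize with n_boot", {
  fx <- tiny_counts(30, 90, 2, seed = 11, lambda = 0.8)
  prof <- bootstrap_profile(fx$counts, fx$labels, n_boot = 1000, seed = 3)
  pct <- percent_expressed(fx$counts, fx$labels)
  expect_true(all(pct[prof$robust_mask] > 0))
  ## one cell type: quadrupling the resamples moves 95% endpoints < 5% relative
  prof5 <- bootstrap_profile(fx$counts, fx$labels, n_boot = 4000, seed = 3)
  hi1 <- prof$ci[["0.95"]]$high[, 1]
  hi5 <- prof5$ci[["0.95"]]$high[, 1]
  keep <- hi5 > 0
  expect_lt(max(abs(hi1[keep] - hi5[keep]) / hi5[keep]), 0.05)
})
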
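test_that("compute_n applies the ceiling formula", {
  expect_identical(compute_n(301, 0.3, 15), 7L)
  expect_identical(compute_n(1000, 0.3, 15), 20L)
  expect_identical(compute_n(10, 0.3, 15), 1L)
})

test_that("random_partition is uniform, non-empty and deterministic", {
  set.seed(21)
  lab <- random_partition(10000, 15)
  sizes <- tabulate(lab, 15)
  expect_true(all(abs(sizes - 10000 / 15) <
                    5 * sqrt(10000 * (1 / 15) * (14 / 15))))
  set.seed(5); a <- random_partition(100, 7)
  set.seed(5); b <- random_partition(100, 7)
  expect_identical(a, b)
  set.seed(6)
  expect_setequal(random_partition(2, 2), 1:2)
  expect_error(random_partition(3, 5), "cannot partition")
})

test_that("balanced training over- and under-samples to exactly n per cluster", {
  set.seed(22)
  X <- matrix(runif(60 * 8), 60, 8,
              dimnames = list(paste0("c", 1:60), paste0("g", 1:8)))
  labels <- c(rep(1L, 3), rep(2L, 50), rep(3L, 7))
  tr <- build_balanced_training(X, labels, n = 5)
  expect_identical(nrow(tr$x), 15L)
  expect_true(all(table(tr$y) == 5))
  small <- tr$rows[tr$y == 1]           # cluster of 3, oversampled
  expect_true(all(small %in% 1:3))
  expect_true(anyDuplicated(small) > 0)
  big <- tr$rows[tr$y == 2]             # cluster of 50, distinct draws
  expect_identical(anyDuplicated(big), 0L)
  gappy <- c(rep(1L, 3), rep(2L, 50), rep(4L, 7))  # cluster 3 empty
  expect_error(build_balanced_training(X, gappy, 5), "empty")
})

test_that("training sets have k*n rows with n rows per label", {
  set.seed(23)
  X <- matrix(runif(200), 25, 8,
              dimnames = list(paste0("c", 1:25), paste0("g", 1:8)))
  labels <- rep(1:4, c(10, 6, 5, 4))
  tr <- build_balanced_training(X, labels, n = 7)
  expect_identical(nrow(tr$x), 28L)
  expect_true(all(table(tr$y) == 7))
})

test_that("train_and_project reproduces separable blob labels exactly", {
  set.seed(31)
  lab <- rep(1:2, each = 50)
  # each blob expresses its own gene: separable by an origin hyperplane
  x <- rbind(cbind(rnorm(50, 10, 0.5), rnorm(50, 0.5, 0.2)),
             cbind(rnorm(50, 0.5, 0.2), rnorm(50, 10, 0.5)))
  x[x < 0] <- 0
  dimnames(x) <- list(sprintf("c%03d", 1:100), c("g1", "g2"))
  fx <- list(x = x, labels = lab)
  tr <- build_balanced_training(fx$x, fx$labels, n = 15)
  pr <- train_and_project(fx$x, tr, C = 0.3)
  expect_equal(adjusted_rand_index(pr$labels, fx$labels), 1.0)
  expect_true(all(abs(rowSums(pr$P) - 1) < 1e-9))
  expect_identical(pr$labels, max.col(pr$P, ties.method = "first"))
})

test_that("smaller C yields sparser weight matrices", {
  fx <- make_blobs(k = 3, per = 40, M = 30, sep = 8, sd = 0.5, seed = 32)
  set.seed(32)
  tr <- build_balanced_training(fx$x, fx$labels, n = 12)
  nnz <- vapply(c(0.01, 0.3, 10), function(C) {
    # very small C may zero out the whole weight matrix, with a warning
    pr <- suppressWarnings(train_and_project(fx$x, tr, C = C))
    length(pr$model$weights@x)
  }, numeric(1))
  expect_true(all(diff(nnz) >= 0))  # non-decreasing in C
  expect_lt(nnz[1], nnz[2])
})

test_that("ICP converges to a perfect self-projection on matched blobs", {
  fx <- make_blobs(k = 5, per = 50, M = 50, sep = 10, sd = 0.5, seed = 42)
  res <- run_icp(fx$x, icp_params(k = 5, seed = 1))
  expect_gte(max(res$ari_trace), 0.99)
  expect_lte(res$cycles, 30)
  expect_equal(adjusted_rand_index(res$S_proj, fx$labels), 1.0)
})

test_that("ICP results are bit-identical under a repeated seed", {
  fx <- small_fixture()
  X <- apply_gene_filter(log_normalize(fx$counts))$matrix
  a <- run_icp(X, icp_params(seed = 77, max_epochs = 12))
  b <- run_icp(X, icp_params(seed = 77, max_epochs = 12))
  expect_identical(a$P, b$P)
  expect_identical(a$S_proj, b$S_proj)
  expect_identical(a$ari_trace, b$ari_trace)
})

test_that("ICP guards degenerate inputs", {
  X <- matrix(runif(40), 10, 4,
              dimnames = list(paste0("c", 1:10), paste0("g", 1:4)))
  expect_error(run_icp(X, icp_params(k = 15)), "non-empty clusters")
  X[, 2] <- 0
  expect_error(run_icp(X, icp_params(k = 3)), "unexpressed")
})
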
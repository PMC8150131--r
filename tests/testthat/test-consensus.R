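test_that("ensemble is deterministic across thread counts and run-distinct", {
  fx <- make_blobs(k = 3, per = 30, M = 20, sep = 10, sd = 0.5, seed = 51)
  params <- icp_params(k = 3, seed = 9, max_epochs = 15)
  e1 <- run_icp_ensemble(fx$x, params, L = 2, threads = 1)
  e2 <- run_icp_ensemble(fx$x, params, L = 2, threads = 2)
  expect_identical(lapply(e1, `[[`, "P"), lapply(e2, `[[`, "P"))
  expect_identical(lapply(e1, `[[`, "S_proj"), lapply(e2, `[[`, "S_proj"))
  seeds <- vapply(e1, `[[`, integer(1), "seed")
  expect_identical(anyDuplicated(seeds), 0L)
})

test_that("joint matrix concatenates run blocks with row sums L", {
  fx <- make_blobs(k = 4, per = 25, M = 20, sep = 10, sd = 0.5, seed = 52)
  ens <- run_icp_ensemble(fx$x, icp_params(k = 4, seed = 2,
                                           max_epochs = 15), L = 3)
  joint <- build_joint_matrix(ens)
  expect_identical(dim(joint), c(100L, 12L))
  expect_true(all(abs(rowSums(joint) - 3) < 1e-6))
  single <- build_joint_matrix(ens[1])
  expect_equal(unname(single), unname(ens[[1]]$P))
  bad <- ens
  bad[[2]]$P <- bad[[2]]$P[-1, ]
  expect_error(build_joint_matrix(bad), "mismatch at run 2")
})

test_that("pca_scores agrees with an SVD oracle after sign alignment", {
  set.seed(53)
  J <- matrix(rnorm(50 * 30), 50, 30)
  p <- 10
  res <- pca_scores(J, p)
  Xc <- sweep(J, 2, colMeans(J), "-")
  sv <- svd(Xc)
  oracle <- sv$u[, 1:p] %*% diag(sv$d[1:p])
  for (j in 1:p) {  # align per-column signs before comparing
    if (sum(abs(oracle[, j] - res$scores[, j])) >
        sum(abs(oracle[, j] + res$scores[, j])))
      oracle[, j] <- -oracle[, j]
  }
  expect_equal(plain_scores(res$scores), oracle, tolerance = 1e-8)
  expect_equal(res$eigenvalues, sv$d[1:p]^2, tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))
  expect_true(all(res$eigenvalues >= -1e-9))
  expect_true(all(abs(colMeans(Xc)) < 1e-12))
})

test_that("pca_scores rejects p beyond dimension or rank", {
  set.seed(54)
  J <- matrix(rnorm(20 * 8), 20, 8)
  expect_error(pca_scores(J, 9), "p must lie")
  low_rank <- cbind(J[, 1:3], J[, 1:3] %*% matrix(rnorm(9), 3))
  expect_error(pca_scores(low_rank, 5), "smaller p")
})

test_that("ward linkage merges tight pairs last and non-decreasingly", {
  pts <- matrix(c(0, 0.1, 20, 20.1, 0, 0, 0, 0), 4, 2,
                dimnames = list(paste0("c", 1:4), NULL))
  hc <- ward_linkage(pts)
  expect_true(all(diff(hc$height) >= 0))
  expect_identical(length(unique(cutree(hc, 2)[1:2])), 1L)  # pair together
  expect_identical(length(unique(cut_tree(hc, 2))), 2L)
  two <- ward_linkage(pts[1:2, ])
  expect_identical(length(two$height), 1L)
  expect_error(ward_linkage(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("cut_tree yields K non-empty nested clusters", {
  fx <- make_blobs(k = 3, per = 20, M = 5, sep = 12, sd = 0.3, seed = 55)
  hc <- ward_linkage(fx$x)
  for (K in 2:6) {
    labs <- cut_tree(hc, K)
    expect_identical(length(unique(labs)), as.integer(K))
  }
  l4 <- cut_tree(hc, 4); l5 <- cut_tree(hc, 5)
  # refinement: cells sharing a 5-cluster share a 4-cluster
  expect_true(all(tapply(l4, l5, function(v) length(unique(v))) == 1))
  expect_identical(length(unique(cut_tree(hc, nrow(fx$x)))), nrow(fx$x))
  expect_error(cut_tree(hc, 1), "K must lie")
})

test_that("silhouette selection recovers blob counts with full profile", {
  fx <- make_blobs(k = 2, per = 30, M = 10, sep = 12, sd = 0.4, seed = 56)
  hc <- ward_linkage(fx$x)
  sel <- select_k_silhouette(fx$x, hc, 2:10)
  expect_identical(sel$K_best, 2L)
  expect_identical(nrow(sel$profile), 9L)
  fx5 <- make_blobs(k = 5, per = 25, M = 20, sep = 12, sd = 0.4, seed = 57)
  hc5 <- ward_linkage(fx5$x)
  expect_identical(select_k_silhouette(fx5$x, hc5, 2:12)$K_best, 5L)
  expect_error(select_k_silhouette(fx$x, hc, 70:80), "empty K search")
})

test_that("consensus labels are invariant to run concatenation order", {
  fx <- make_blobs(k = 3, per = 30, M = 20, sep = 10, sd = 0.5, seed = 58)
  ens <- run_icp_ensemble(fx$x, icp_params(k = 3, seed = 4,
                                           max_epochs = 15), L = 4)
  labs_for <- function(order) {
    pca <- pca_scores(build_joint_matrix(ens[order]), p = 5)
    cut_tree(ward_linkage(pca$scores), 3)
  }
  a <- labs_for(1:4)
  b <- labs_for(c(3, 1, 4, 2))
  expect_equal(adjusted_rand_index(a, b), 1.0)
})
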
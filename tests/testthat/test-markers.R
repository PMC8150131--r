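test_that("rank-sum p-values match exact small-sample results", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5)), 1.0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("rank-sum p-values match full-permutation enumeration", {
  set.seed(71)
  for (i in 1:100) {
    x <- rnorm(sample(2:8, 1))
    y <- rnorm(sample(2:8, 1))
    expect_equal(wilcoxon_rank_sum(x, y), wilcox_perm_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("log2 fold change is 0 at equality, antisymmetric, count-invertible", {
  x <- log1p(c(3, 3, 3)); y <- log1p(c(1, 1, 1))
  expect_equal(log2_fold_change(x, x), 0.0)
  expect_equal(log2_fold_change(x, y), 1.0)  # (3+1)/(1+1) = 2
  expect_equal(log2_fold_change(y, x), -1.0)
  set.seed(72)
  a <- log1p(rpois(30, 4)); b <- log1p(rpois(40, 2))
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("Bonferroni adjustment is min(1, p*m) over tests performed", {
  fx <- planted_fixture()
  filters <- filter_params(min_pct = 0, min_abs_log2fc = 0)
  sub <- fx$x[, 1:100]
  tab <- find_all_gene_markers(sub, fx$truth, filters)
  m <- nrow(tab)
  expect_identical(m, 100L * 5L)  # zero filters: every gene, every cluster
  expect_equal(tab$adj_p_value, pmin(1, tab$p_value * m))
  expect_true(all(tab$adj_p_value >= tab$p_value))
  expect_true(all(tab$pct_in >= 0 & tab$pct_in <= 1))
})

test_that("planted markers are recovered with positive fold change", {
  fx <- planted_fixture()
  tab <- find_all_gene_markers(fx$x, fx$truth)
  for (pop in names(fx$marker_map)) {
    markers <- intersect(fx$marker_map[[pop]], colnames(fx$x))
    rows <- tab[tab$cluster_id == pop & tab$gene_id %in% markers, ]
    expect_identical(nrow(rows), length(markers))
    expect_true(all(rows$adj_p_value < 0.01))
    expect_true(all(rows$log2fc > 0))
  }
})

test_that("two-set comparison matches one-vs-rest for a 2-cluster partition", {
  fx <- planted_fixture()
  two <- ifelse(fx$truth <= 2, 1L, 2L)
  sub <- fx$x[, 1:300]
  all_tab <- find_all_gene_markers(sub, two, filter_params(0, 0))
  ab <- find_gene_markers(sub, two, 1L, 2L, filter_params(0, 0))
  one <- all_tab[all_tab$cluster_id == "1", ]
  merged <- merge(one, ab, by = "gene_id")
  expect_equal(merged$p_value.x, merged$p_value.y)
  expect_equal(merged$log2fc.x, merged$log2fc.y)
})

test_that("marker guards: overlapping sets, missing ids, tiny clusters", {
  fx <- planted_fixture()
  expect_error(find_gene_markers(fx$x, fx$truth, c(1, 2), c(2, 3)),
               "disjoint")
  expect_error(find_gene_markers(fx$x, fx$truth, 1, 99), "not present")
  labels <- fx$truth
  labels[1] <- 99L  # singleton cluster is skipped with a warning
  expect_warning(tab <- find_all_gene_markers(fx$x[, 1:50], labels,
                                              filter_params(0, 0)),
                 "fewer than 2")
  expect_false("99" %in% tab$cluster_id)
})

test_that("a uniformly expressed gene yields p near 1 and no discovery", {
  set.seed(73)
  X <- log1p(matrix(rpois(200 * 50, 2), 200, 50,
                    dimnames = list(paste0("c", 1:200),
                                    paste0("g", 1:50))))
  labels <- rep(1:2, each = 100)
  tab <- find_all_gene_markers(X, labels, filter_params(0, 0))
  expect_true(all(tab$adj_p_value > 0.05))
})
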
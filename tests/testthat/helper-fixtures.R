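# Shared fixtures, built in code and memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Well-separated Gaussian blobs clipped to non-negative values:
# populations differ in every gene, the geometry ICP projects perfectly.
make_blobs <- function(k = 5, per = 50, M = 50, sep = 10, sd = 0.5,
                       seed = 42) {
  set.seed(seed)
  centers <- matrix(runif(k * M), k) * sep
  lab <- rep(seq_len(k), each = per)
  X <- centers[lab, , drop = FALSE] +
    matrix(rnorm(k * per * M, 0, sd), k * per)
  X[X < 0] <- 0
  dimnames(X) <- list(sprintf("cell_%03d", seq_len(k * per)),
                      sprintf("gene_%03d", seq_len(M)))
  list(x = X, labels = lab)
}

# Reference planted-population count fixture, log-normalized and filtered.
planted_fixture <- function() {
  memo("planted", {
    sim <- simulate_counts(sim_spec(seed = 101L))
    X <- apply_gene_filter(log_normalize(sim$counts))$matrix
    list(x = X, truth = sim$truth, marker_map = sim$marker_map, sim = sim)
  })
}

# Small planted fixture for loop-contract properties.
small_fixture <- function(seed = 202L) {
  sim <- simulate_counts(sim_spec(N = 300L, M = 500L, K_true = 4L,
                                  markers_per_pop = 10L, seed = seed))
  list(counts = sim$counts, truth = sim$truth)
}

# Random partition pair for ARI property tests.
random_label_pair <- function(N, ka, kb) {
  list(a = sample.int(ka, N, replace = TRUE),
       b = sample.int(kb, N, replace = TRUE))
}

# Plain numeric matrix from a score matrix (drops handshake attributes).
plain_scores <- function(m) {
  m <- as.matrix(m)
  attr(m, "consensus_checksum") <- NULL
  unname(m)
}

# Exhaustive pair-counting ARI oracle: classifies all N(N-1)/2 cell pairs
# as together/apart in each partition and applies the chance-corrected
# agreement form.  Independent of the contingency-table implementation.
ari_pair_oracle <- function(a, b) {
  N <- length(a)
  pairs <- utils::combn(N, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1.0)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Full-permutation two-sided Wilcoxon rank-sum oracle (no ties assumed):
# enumerates every assignment of the pooled values to the two groups.
wilcox_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n)])
  u_obs <- r_obs - n * (n + 1) / 2
  sets <- utils::combn(length(pooled), n)
  u_all <- apply(sets, 2, function(idx)
    sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  pl <- mean(u_all <= u_obs)
  pg <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pg))
}
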
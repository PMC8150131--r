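#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting similarity between two clusterings of the
#' same cells, computed from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - [\sum_i\binom{a_i}{2}
#'   \sum_j\binom{b_j}{2}]/\binom{N}{2}}{\frac12[\sum_i\binom{a_i}{2} +
#'   \sum_j\binom{b_j}{2}] - [\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}]/
#'   \binom{N}{2}}}
#' where \eqn{n_{ij}} counts cells shared by cluster i of `a` and cluster j
#' of `b`, and \eqn{a_i}, \eqn{b_j} are the marginal cluster sizes.  The
#' index is 1 exactly when the partitions are identical up to label
#' renaming, and has expectation 0 for independent random partitions.
#' When both partitions consist of a single cluster (or both are
#' all-singletons) the formula is 0/0; the partitions are then identical, so
#' 1 is returned.
#'
#' Empty clusters (label values with no members) are permitted and ignored,
#' as are the particular label values: only the induced grouping matters.
#'
#' @param a,b cluster-label vectors of equal length (any atomic type).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions have different lengths: ", length(a), " vs ", length(b))
  N <- length(a)
  if (N < 2L) stop("need at least 2 cells")
  tab <- table(a, b)
  sum_nij <- sum(choose(tab, 2))
  sum_ai <- sum(choose(rowSums(tab), 2))
  sum_bj <- sum(choose(colSums(tab), 2))
  expected <- sum_ai * sum_bj / choose(N, 2)
  denom <- 0.5 * (sum_ai + sum_bj) - expected
  if (denom == 0) return(1.0)  # both single-cluster or both all-singletons
  (sum_nij - expected) / denom
}

# Mean silhouette width from a precomputed dist object.
.mean_sil_dist <- function(labels, D) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least 2 non-empty clusters")
  sil <- cluster::silhouette(labels, dist = D)
  mean(sil[, "sil_width"])
}

#' Mean silhouette width of a labelled point set
#'
#' Average over cells of \eqn{(b - a) / \max(a, b)} with Euclidean
#' distances, where a is the mean distance to the cell's own cluster and b
#' the smallest mean distance to another cluster.  Cells in singleton
#' clusters contribute 0.  For more than `max_cells` cells a uniform
#' subsample (drawn from the current RNG state) is scored instead, keeping
#' the cost of repeated evaluation bounded.
#'
#' @param points N x p numeric matrix.
#' @param labels length-N cluster labels with at least 2 non-empty clusters.
#' @param max_cells subsampling cap (default 10000).
#' @return mean silhouette width in \[-1, 1\].
#' @export
mean_silhouette <- function(points, labels, max_cells = 1e4) {
  points <- as.matrix(points)
  if (nrow(points) != length(labels))
    stop("points and labels disagree in length")
  if (nrow(points) > max_cells) {
    idx <- sample.int(nrow(points), max_cells)
    points <- points[idx, , drop = FALSE]
    labels <- labels[idx]
  }
  .mean_sil_dist(labels, dist(points))
}
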
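#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both samples have at most 25 observations and no
#' ties are present; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction.  Degenerate inputs with
#' zero variance (all observations identical) carry no evidence and return
#' p = 1.
#'
#' @param x,y non-empty numeric vectors.
#' @return two-sided p-value in \[0, 1\].
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  exact <- length(x) <= 25L && length(y) <= 25L && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  if (is.na(p)) p <- 1.0  # zero-variance degenerate case
  min(p, 1.0)
}

#' Log2 fold change between two groups on log-normalized data
#'
#' Computes `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`:
#' expression is mapped back to the (scaled) count scale before averaging,
#' and a pseudo-count of 1 guards all-zero groups.  The estimator is
#' antisymmetric under swapping the groups.
#'
#' @param in_values,out_values log-normalized expression of one gene in the
#'   two groups.
#' @return signed log2 fold change (positive = higher in `in_values`).
#' @export
log2_fold_change <- function(in_values, out_values) {
  log2((mean(expm1(in_values)) + 1) / (mean(expm1(out_values)) + 1))
}

#' Marker-test filter settings
#'
#' Genes enter the rank-sum test only if detected in at least
#' `min_pct` of the in-group cells and showing `|log2 FC| >=
#' min_abs_log2fc`; both pre-test filters reduce the number of tests (and
#' hence the Bonferroni factor).  `max_cells_per_group` optionally
#' downsamples each side of a comparison before testing.
#'
#' @param min_pct minimum in-group detection fraction (default 0.10).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 0.25).
#' @param max_cells_per_group per-group cell cap (default `Inf`, off).
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_pct = 0.10, min_abs_log2fc = 0.25,
                          max_cells_per_group = Inf) {
  stopifnot(min_pct >= 0, min_pct <= 1, min_abs_log2fc >= 0,
            max_cells_per_group >= 2)
  structure(list(min_pct = min_pct, min_abs_log2fc = min_abs_log2fc,
                 max_cells_per_group = max_cells_per_group),
            class = "filter_params")
}

# Per-gene statistics for one in-group vs out-group comparison.
# Returns a data.frame without multiple-testing adjustment (done globally).
.marker_stats <- function(X, in_idx, out_idx, cluster_id, filters) {
  cap <- filters$max_cells_per_group
  if (is.finite(cap)) {
    if (length(in_idx) > cap) in_idx <- sample(in_idx, cap)
    if (length(out_idx) > cap) out_idx <- sample(out_idx, cap)
  }
  Xin <- X[in_idx, , drop = FALSE]
  Xout <- X[out_idx, , drop = FALSE]
  mu_in <- Matrix::colMeans(expm1(Xin))
  mu_out <- Matrix::colMeans(expm1(Xout))
  l2fc <- log2((mu_in + 1) / (mu_out + 1))
  pct_in <- Matrix::colMeans(Xin > 0)
  pct_out <- Matrix::colMeans(Xout > 0)
  keep <- pct_in >= filters$min_pct & abs(l2fc) >= filters$min_abs_log2fc
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  Din <- as.matrix(Xin[, idx, drop = FALSE])
  Dout <- as.matrix(Xout[, idx, drop = FALSE])
  p <- vapply(seq_along(idx), function(j)
    wilcoxon_rank_sum(Din[, j], Dout[, j]), numeric(1))
  data.frame(gene_id = colnames(X)[idx],
             cluster_id = cluster_id,
             log2fc = l2fc[idx],
             p_value = p,
             pct_in = pct_in[idx],
             pct_out = pct_out[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

.finalize_marker_table <- function(parts) {
  if (length(parts) == 0L)
    return(data.frame(gene_id = character(0), cluster_id = character(0),
                      log2fc = numeric(0), p_value = numeric(0),
                      adj_p_value = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), stringsAsFactors = FALSE))
  tab <- do.call(rbind, parts)
  m <- nrow(tab)  # Bonferroni over the tests actually performed
  tab$adj_p_value <- pmin(1, tab$p_value * m)
  tab <- tab[order(tab$cluster_id, tab$adj_p_value, -tab$log2fc), ]
  rownames(tab) <- NULL
  tab[, c("gene_id", "cluster_id", "log2fc", "p_value", "adj_p_value",
          "pct_in", "pct_out")]
}

#' Find marker genes for every cluster (one-versus-rest)
#'
#' For each cluster, compares its cells against all other cells with the
#' Wilcoxon rank-sum test on log-normalized expression.  Genes failing the
#' pre-test filters are excluded before testing, and the Bonferroni factor
#' is the number of (gene, cluster) tests actually performed.  Clusters
#' with fewer than 2 cells are skipped with a warning.
#'
#' @param X log-normalized cells x genes matrix.
#' @param labels length-N cluster labels with at least 2 non-empty clusters.
#' @param filters a [filter_params()] object.
#' @param seed optional seed for the downsampling cap (if unset the current
#'   RNG state is used).
#' @return data.frame with columns gene_id, cluster_id, log2fc, p_value,
#'   adj_p_value, pct_in, pct_out, sorted by (cluster_id, adj_p_value,
#'   -log2fc).
#' @export
find_all_gene_markers <- function(X, labels, filters = filter_params(),
                                  seed = NULL) {
  X <- .validate_expression(X)
  if (nrow(X) != length(labels)) stop("labels and X disagree in length")
  if (!is.null(seed)) set.seed(seed)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stop("need at least 2 non-empty clusters")
  parts <- list()
  for (cl in clusters) {
    in_idx <- which(labels == cl)
    if (length(in_idx) < 2L) {
      warning("skipping cluster ", cl, " with fewer than 2 cells")
      next
    }
    parts[[as.character(cl)]] <-
      .marker_stats(X, in_idx, which(labels != cl), as.character(cl),
                    filters)
  }
  .finalize_marker_table(parts)
}

#' Find marker genes between two arbitrary sets of clusters
#'
#' Pools the cells of the clusters in `set_a` and of those in `set_b` and
#' applies the same test, filter and Bonferroni machinery as
#' [find_all_gene_markers()].  Positive log2 fold changes mean higher
#' expression in `set_a`.
#'
#' @inheritParams find_all_gene_markers
#' @param set_a,set_b disjoint, non-empty sets of cluster ids present in
#'   `labels`.
#' @return marker data.frame (cluster_id is the `set_a` ids joined by "+").
#' @export
find_gene_markers <- function(X, labels, set_a, set_b,
                              filters = filter_params(), seed = NULL) {
  X <- .validate_expression(X)
  if (nrow(X) != length(labels)) stop("labels and X disagree in length")
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("both cluster sets must be non-empty")
  if (length(intersect(set_a, set_b)) > 0L)
    stop("cluster sets must be disjoint")
  missing <- setdiff(c(set_a, set_b), unique(labels))
  if (length(missing))
    stop("cluster id(s) not present in labels: ",
         paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  in_idx <- which(labels %in% set_a)
  out_idx <- which(labels %in% set_b)
  if (length(in_idx) < 2L || length(out_idx) < 2L)
    stop("each pooled set must contain at least 2 cells")
  part <- .marker_stats(X, in_idx, out_idx,
                        paste(set_a, collapse = "+"), filters)
  .finalize_marker_table(if (is.null(part)) list() else list(part))
}
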
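#' Run an ensemble of independent ICP runs
#'
#' Runs ICP `L` times with different seeds derived deterministically from
#' the base seed (`params$seed`): a seed vector is drawn up front, so the
#' result is bit-identical for any `threads` value or scheduling order.
#' Individual run failures are tolerated up to 10% of `L` (with warnings);
#' beyond that the ensemble aborts.
#'
#' @param X gene-filtered cells x genes matrix.
#' @param params an [icp_params()] object; `params$seed` is the base seed.
#' @param L number of runs (method default 200; smaller values are useful
#'   for quick looks and testing).
#' @param threads number of worker processes (forked; 1 = serial).
#' @return list of `L` [run_icp()] results, class `icp_ensemble`.
#' @export
run_icp_ensemble <- function(X, params = icp_params(), L = 200L,
                             threads = 1L) {
  stopifnot(L >= 1, threads >= 1)
  X <- .validate_expression(X)
  set.seed(params$seed)
  run_seeds <- sample.int(2147483646L, L)
  worker <- function(l) {
    p <- params
    p$seed <- run_seeds[l]
    tryCatch(run_icp(X, p),
             error = function(e) structure(list(index = l,
                                                message = conditionMessage(e)),
                                           class = "icp_failure"))
  }
  results <- if (threads > 1L) {
    parallel::mclapply(seq_len(L), worker, mc.cores = threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(L), worker)
  }
  failed <- vapply(results, inherits, logical(1), "icp_failure")
  if (any(failed)) {
    msgs <- vapply(results[failed], function(f)
      sprintf("run %d: %s", f$index, f$message), character(1))
    if (mean(failed) > 0.10)
      stop("ICP ensemble failed (", sum(failed), "/", L, " runs):\n",
           paste(msgs, collapse = "\n"))
    warning("dropping ", sum(failed), " failed ICP run(s):\n",
            paste(msgs, collapse = "\n"))
    results <- results[!failed]
  }
  structure(results, class = "icp_ensemble", base_seed = params$seed)
}

#' Concatenate ensemble probability matrices into the joint matrix
#'
#' Horizontally concatenates the N x k probability matrices of the runs, in
#' run order, into the N x (k*L) joint matrix.  Each run's block is
#' row-stochastic, so every row of the joint matrix sums to L.
#'
#' @param results list of [run_icp()] results (e.g. an `icp_ensemble`).
#' @return N x (k*L) numeric matrix with per-run column groups.
#' @export
build_joint_matrix <- function(results) {
  stopifnot(length(results) >= 1)
  dims <- vapply(results, function(r) dim(r$P), integer(2))
  if (length(unique(dims[1L, ])) != 1L || length(unique(dims[2L, ])) != 1L)
    stop("probability-matrix shape mismatch at run ",
         which(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L])[1L])
  blocks <- lapply(seq_along(results), function(l) {
    B <- results[[l]]$P
    colnames(B) <- sprintf("run%d_%s", l, colnames(B))
    B
  })
  do.call(cbind, blocks)
}

#' PCA scores of the joint probability matrix
#'
#' Columns of `joint` are centered to mean zero and the top-p eigenpairs of
#' the (columns x columns) cross-product are extracted (dense symmetric
#' eigendecomposition up to 2000 columns, iterative Lanczos beyond).  Scores
#' are the centered matrix projected on the eigenvectors.  Eigenvector signs
#' are fixed so the largest-magnitude loading of each component is positive,
#' making the result deterministic.  Requesting more components than the
#' matrix rank is an error (choose a smaller p).
#'
#' @param joint N x (k*L) joint probability matrix.
#' @param p number of principal components (method default 50).
#' @return list with `scores` (N x p) and `eigenvalues` (non-increasing,
#'   length p).
#' @export
pca_scores <- function(joint, p = 50L) {
  joint <- as.matrix(joint)
  n <- nrow(joint)
  m <- ncol(joint)
  if (p < 1L || p > min(n - 1L, m))
    stop("p must lie in [1, min(N - 1, ncol)] = [1, ", min(n - 1L, m), "]")
  Xc <- sweep(joint, 2L, colMeans(joint), "-")
  if (m <= 2000L) {
    eig <- eigen(crossprod(Xc), symmetric = TRUE)
    values <- eig$values[seq_len(p)]
    vectors <- eig$vectors[, seq_len(p), drop = FALSE]
    rank_tol <- max(eig$values) * 1e-10
  } else {
    eig <- RSpectra::eigs_sym(crossprod(Xc), k = p, which = "LM")
    values <- eig$values
    vectors <- eig$vectors
    rank_tol <- max(values) * 1e-10
  }
  if (values[p] <= rank_tol)
    stop("rank of the joint matrix is below p = ", p,
         "; choose a smaller p")
  for (j in seq_len(p)) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  scores <- Xc %*% vectors
  dimnames(scores) <- list(rownames(joint), sprintf("PC%d", seq_len(p)))
  attr(scores, "consensus_checksum") <-
    c(dim(scores), signif(sum(scores * scores), 12))
  list(scores = scores, eigenvalues = values)
}

#' Ward hierarchical clustering of the consensus scores
#'
#' Agglomerates cells by the Ward minimum-variance criterion on Euclidean
#' distances in the consensus PCA space (the squared-distance "ward.D2"
#' update, the criterion computed by the fast implementations this method
#' family uses).
#'
#' @param scores N x p score matrix with cell ids as row names.
#' @return an `hclust` merge tree.
#' @export
ward_linkage <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least 2 cells")
  if (!all(is.finite(scores))) stop("non-finite values in scores")
  hclust(dist(scores), method = "ward.D2")
}

#' Cut the consensus dendrogram into K clusters
#'
#' @param linkage an `hclust` tree from [ward_linkage()].
#' @param K number of clusters, `2 <= K <= N` (cuts at successive K are
#'   nested: the (K+1)-cut refines the K-cut).
#' @return integer vector of K non-empty cluster labels.
#' @export
cut_tree <- function(linkage, K) {
  stopifnot(inherits(linkage, "hclust"))
  N <- length(linkage$order)
  if (K < 2L || K > N)
    stop("K must lie in [2, ", N, "]")
  cutree(linkage, k = K)
}

#' Select the number of consensus clusters by the silhouette method
#'
#' Cuts the dendrogram at every K in `search_range` (clipped to
#' `[2, N - 1]`) and scores each cut by mean silhouette width on the
#' consensus scores; returns the maximizing K, with ties broken toward the
#' smallest K (parsimony), together with the full profile.  Distances are
#' computed once; above `max_cells` cells a uniform subsample (current RNG
#' state) is scored.
#'
#' @param scores N x p consensus score matrix.
#' @param linkage the matching `hclust` tree.
#' @param search_range candidate K values (default `2:50`).
#' @param max_cells silhouette subsampling cap.
#' @return list with `K_best` and `profile` (data.frame of K and
#'   mean_silhouette).
#' @export
select_k_silhouette <- function(scores, linkage, search_range = 2:50,
                                max_cells = 1e4) {
  scores <- as.matrix(scores)
  N <- nrow(scores)
  search_range <- sort(unique(as.integer(search_range)))
  search_range <- search_range[search_range >= 2L & search_range <= N - 1L]
  if (length(search_range) == 0L)
    stop("empty K search range after clipping to [2, N - 1]")
  idx <- seq_len(N)
  if (N > max_cells) idx <- sort(sample.int(N, max_cells))
  D <- dist(scores[idx, , drop = FALSE])
  profile <- vapply(search_range, function(K) {
    labels <- cutree(linkage, k = K)[idx]
    if (length(unique(labels)) < 2L) return(NA_real_)
    .mean_sil_dist(labels, D)
  }, numeric(1))
  K_best <- search_range[which.max(profile)]  # first max = smallest K
  list(K_best = K_best,
       profile = data.frame(K = search_range, mean_silhouette = profile))
}
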
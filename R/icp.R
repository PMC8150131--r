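#' ICP parameter set
#'
#' Bundles the tuning parameters of iterative clustering projection.
#' Defaults follow the method's standard settings: `k = 15` initial
#' clusters, training fraction control `d = 0.3`, regularization trade-off
#' `C = 0.3`, and at most `r = 5` consecutive failed reiterations.  `k` and
#' `d` are the main resolution controls; a larger `k` or a smaller `d`
#' raises the resolution of the downstream consensus clustering.
#'
#' @param k initial number of clusters (>= 2).
#' @param d training-set size control in (0, 1); each cluster contributes
#'   `n = ceiling(N * d / k)` training cells.
#' @param C positive trade-off between correct classification and L1
#'   regularization; smaller values select fewer genes.
#' @param r maximum number of consecutive rejected reiterations before the
#'   run stops.
#' @param max_epochs safety cap on the total number of train-project cycles.
#' @param seed integer seed driving the initial partition and every
#'   resampling of the run.
#' @param tol convergence threshold forwarded to the logistic-regression
#'   solver (glmnet `thresh`).
#' @return an object of class `icp_params`.
#' @export
icp_params <- function(k = 15L, d = 0.3, C = 0.3, r = 5L,
                       max_epochs = 200L, seed = 1L, tol = 1e-6) {
  stopifnot(k >= 2, d > 0, d < 1, C > 0, r >= 1, max_epochs >= 1)
  structure(list(k = as.integer(k), d = d, C = C, r = as.integer(r),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), tol = tol),
            class = "icp_params")
}

#' Uniform random partition of N cells into k clusters
#'
#' Each cell's label is drawn i.i.d. uniformly over the k clusters.  Draws
#' leaving any cluster empty are rejected and redrawn (up to `max_tries`
#' attempts), so the returned partition always has exactly k non-empty
#' clusters.  Uses the current RNG state.
#'
#' @param N number of cells (>= k).
#' @param k number of clusters (>= 2).
#' @param max_tries redraw bound for the non-empty guard.
#' @return integer vector of labels in `1:k`.
#' @export
random_partition <- function(N, k, max_tries = 1000L) {
  if (k < 2L) stop("k must be >= 2")
  if (N < k) stop("cannot partition ", N, " cells into ", k,
                  " non-empty clusters")
  for (i in seq_len(max_tries)) {
    labels <- sample.int(k, N, replace = TRUE)
    if (length(unique(labels)) == k) return(labels)
  }
  stop("failed to draw a partition with ", k,
       " non-empty clusters in ", max_tries, " tries")
}

#' Per-cluster training-set size
#'
#' `n = ceiling(N * d / k)`: the number of cells each cluster contributes to
#' the balanced training set.
#'
#' @param N total number of cells.
#' @param d training fraction control in (0, 1).
#' @param k number of clusters.
#' @return integer n >= 1.
#' @export
compute_n <- function(N, d, k) {
  stopifnot(N >= 1, d > 0, d < 1, k >= 2)
  as.integer(ceiling(N * d / k))
}

#' Build a class-balanced training set
#'
#' Draws exactly `n` cells from every cluster of `labels`: clusters with
#' fewer than n members are oversampled with replacement, clusters with at
#' least n members are downsampled without replacement.  The balancing keeps
#' all k classes represented with equal weight, which protects the
#' one-vs-rest classifier from collapsing small clusters.  Rows are
#' assembled cluster by cluster and then shuffled (current RNG state) so the
#' solver never sees a class-sorted design.
#'
#' @param X cells x genes matrix.
#' @param labels length-N integer labels in `1:k` with no empty cluster.
#' @param n per-cluster sample count.
#' @return list with `x` (the (k*n) x M training matrix), `y` (factor of
#'   length k*n with levels `1:k`), `rows` (source row indices) and `n`.
#' @export
build_balanced_training <- function(X, labels, n) {
  stopifnot(n >= 1)
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0))
    stop("empty cluster(s) in partition: ",
         paste(which(sizes == 0), collapse = ", "))
  rows <- unlist(lapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    if (length(members) < n) {
      members[sample.int(length(members), n, replace = TRUE)]
    } else {
      members[sample.int(length(members), n)]
    }
  }))
  y <- factor(rep(seq_len(k), each = n), levels = seq_len(k))
  ord <- sample.int(length(rows))
  list(x = X[rows[ord], , drop = FALSE], y = y[ord], rows = rows[ord], n = n)
}

# One-vs-rest L1 logistic regression via glmnet.
#
# The per-class objective is min_w ||w||_1 + C * sum_i log(1 + exp(-y_i
# w'x_i)) with no intercept.  glmnet minimizes (1/n) * logloss +
# lambda * ||w||_1, so the target penalty is lambda = 1 / (n_train * C).
# A short geometric path down to the target lambda is used for warm starts.
.fit_ovr_l1 <- function(x, y, C, tol = 1e-6) {
  k <- nlevels(y)
  n_train <- nrow(x)
  lam <- 1 / (n_train * C)
  path <- lam * c(8, 4, 2, 1)
  W <- vector("list", k)
  for (cl in seq_len(k)) {
    yy <- as.integer(y == levels(y)[cl])
    fit <- tryCatch(
      withCallingHandlers(
        glmnet::glmnet(x, yy, family = "binomial", alpha = 1,
                       lambda = path, intercept = FALSE,
                       standardize = FALSE, thresh = tol),
        # small per-cluster training counts are routine here (n = N*d/k)
        warning = function(w) {
          if (grepl("fewer than 8", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) stop("logistic solver failed for cluster ", cl,
                               ": ", conditionMessage(e), call. = FALSE))
    W[[cl]] <- stats::coef(fit, s = lam)[-1L, 1L, drop = FALSE]
  }
  W <- Matrix::t(do.call(cbind, W))  # k x M
  dimnames(W) <- list(paste0("cluster_", seq_len(k)), colnames(x))
  W
}

#' Train a one-vs-rest L1 logistic classifier and project all cells
#'
#' Fits one L1-regularized, intercept-free logistic-regression weight vector
#' per cluster on the balanced training set (one cluster as positives, the
#' rest as negatives), then scores every cell of `X` against all k
#' classifiers.  The independent per-class sigmoid outputs are renormalized
#' to sum to 1 per cell, giving a row-stochastic probability matrix; the
#' projected label of a cell is the argmax of its row (ties broken toward
#' the lowest cluster id).
#'
#' @param X cells x genes matrix (same gene set as the training matrix).
#' @param training balanced training set from [build_balanced_training()].
#' @param C positive regularization trade-off; lower C selects fewer genes.
#' @param tol solver convergence threshold.
#' @return list with `model` (list of k x M sparse `weights` and `C`),
#'   `labels` (projected partition) and `P` (N x k row-stochastic matrix).
#' @export
train_and_project <- function(X, training, C, tol = 1e-6) {
  if (ncol(X) != ncol(training$x))
    stop("X and training data disagree in gene set")
  W <- .fit_ovr_l1(training$x, training$y, C, tol)
  if (all(W@x == 0))
    warning("all classifier weights are zero; C = ", C, " may be too small")
  scores <- as.matrix(X %*% Matrix::t(W))
  P <- plogis(scores)
  P <- P / rowSums(P)
  dimnames(P) <- list(rownames(X), rownames(W))
  labels <- max.col(P, ties.method = "first")
  list(model = list(weights = W, C = C), labels = labels, P = P)
}

#' Run iterative clustering projection
#'
#' Starting from a uniform random partition into `params$k` clusters, each
#' cycle (i) draws a class-balanced training sample of the current
#' clustering, (ii) trains the one-vs-rest L1 logistic classifier and
#' projects all cells through it, and (iii) compares projection to
#' clustering by the adjusted Rand index (initialized to 0).  The projection
#' is accepted as the next clustering only if the ARI strictly increased
#' *and* the projection still has exactly k non-empty clusters; k
#' preservation is a loop invariant (the class balancing exists to keep k
#' unchanged, so a projection that drops a cluster is never accepted, even
#' on an ARI tie-break).  After a rejection the same clustering is resampled
#' and retrained, up to `params$r` consecutive failures, after which the
#' run stops and the probability matrix and projected clustering of the
#' final train-project cycle are returned (the last computed projection:
#' when `k` exceeds the number of well-separated populations the classifier
#' may concentrate its predictions on fewer than k clusters every cycle, in
#' which case no update is ever accepted yet the returned projection still
#' carries the population structure).
#'
#' @param X gene-filtered cells x genes matrix (every gene expressed in at
#'   least one cell).
#' @param params an [icp_params()] object.
#' @return an object of class `icp_result`: list with `P` (N x k
#'   row-stochastic probability matrix of the final train-project cycle),
#'   `S_proj` (its argmax partition), `ari_trace` (strictly increasing ARI
#'   of the accepted epochs), `weights` (k x M sparse coefficients of the
#'   final cycle), `epochs_run`, `reiterations_used`, `cycles`,
#'   `truncated`, `max_row_sum_dev`, `k_trace` and `seed`.
#' @export
run_icp <- function(X, params = icp_params()) {
  stopifnot(inherits(params, "icp_params"))
  X <- .validate_expression(X)
  if (any(Matrix::colSums(X > 0) == 0))
    stop("X contains unexpressed genes; run apply_gene_filter() first")
  N <- nrow(X)
  k <- params$k
  if (N < k)
    stop("N = ", N, " cells cannot form ", k, " non-empty clusters")
  set.seed(params$seed)
  S <- random_partition(N, k)
  n <- compute_n(N, params$d, k)
  best_ari <- 0
  best <- NULL
  trace <- numeric(0)
  k_trace <- integer(0)
  reiter <- 0L
  cycles <- 0L
  truncated <- FALSE
  max_dev <- 0
  repeat {
    if (cycles >= params$max_epochs) {
      truncated <- TRUE
      break
    }
    cycles <- cycles + 1L
    tr <- build_balanced_training(X, S, n)
    pr <- train_and_project(X, tr, params$C, params$tol)
    max_dev <- max(max_dev, max(abs(rowSums(pr$P) - 1)))
    ari <- adjusted_rand_index(S, pr$labels)
    k_proj <- length(unique(pr$labels))
    if (ari > best_ari && k_proj == k) {
      best_ari <- ari
      trace <- c(trace, ari)
      k_trace <- c(k_trace, k_proj)
      S <- pr$labels
      reiter <- 0L
    } else {
      reiter <- reiter + 1L
      if (reiter >= params$r) break
    }
  }
  structure(list(P = pr$P,
                 S_proj = pr$labels,
                 ari_trace = trace,
                 weights = pr$model$weights,
                 epochs_run = length(trace),
                 reiterations_used = reiter,
                 cycles = cycles,
                 truncated = truncated,
                 max_row_sum_dev = max_dev,
                 k_trace = k_trace,
                 seed = params$seed,
                 params = params),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat("ICP result: ", nrow(x$P), " cells, k = ", ncol(x$P), "\n",
      "  accepted epochs: ", x$epochs_run,
      " (", x$cycles, " train-project cycles",
      if (x$truncated) ", truncated" else "", ")\n",
      "  projection accuracy (final ARI): ",
      if (length(x$ari_trace)) signif(max(x$ari_trace), 4) else NA, "\n",
      "  nonzero weights: ", length(x$weights@x), " / ",
      prod(dim(x$weights)), "\n", sep = "")
  invisible(x)
}
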
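#' Two-dimensional embedding of the consensus space
#'
#' Embeds the N x p consensus PCA scores -- never the raw expression matrix
#' -- in two dimensions with t-SNE or UMAP.  Both methods run
#' single-threaded with a fixed seed, so coordinates are reproducible.
#' When the input carries the checksum attribute attached by
#' [pca_scores()], it is propagated to the result, recording that the
#' embedding was computed from an unmodified consensus score matrix.
#'
#' @param scores N x p numeric matrix (consensus scores).
#' @param method `"tsne"` or `"umap"`.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (N - 1) / 3`.
#' @param n_neighbors,min_dist UMAP neighborhood size and minimum distance.
#' @param seed integer seed for the embedding.
#' @return object of class `embedding_2d`: list with `coords` (N x 2,
#'   columns `dim1`, `dim2`), `method` and `params`.
#' @export
embed_cells <- function(scores, method = c("tsne", "umap"),
                        perplexity = 30, n_neighbors = 15, min_dist = 0.1,
                        seed = 1L) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  N <- nrow(scores)
  if (N < 4L) stop("need at least 4 cells to embed")
  if (!all(is.finite(scores))) stop("non-finite values in scores")
  if (method == "tsne") {
    if (perplexity <= 0 || perplexity >= (N - 1) / 3)
      stop("perplexity must lie in (0, (N - 1) / 3) = (0, ",
           (N - 1) / 3, ")")
    set.seed(seed)
    coords <- Rtsne::Rtsne(scores, dims = 2L, perplexity = perplexity,
                           pca = FALSE, check_duplicates = FALSE,
                           num_threads = 1L, verbose = FALSE)$Y
    params <- list(perplexity = perplexity, seed = seed)
  } else {
    if (n_neighbors < 2 || n_neighbors >= N)
      stop("n_neighbors must lie in [2, N - 1]")
    if (min_dist <= 0) stop("min_dist must be positive")
    set.seed(seed)
    coords <- uwot::umap(scores, n_neighbors = n_neighbors,
                         min_dist = min_dist, n_threads = 1L,
                         n_sgd_threads = 0L, verbose = FALSE)
    params <- list(n_neighbors = n_neighbors, min_dist = min_dist,
                   seed = seed)
  }
  dimnames(coords) <- list(rownames(scores), c("dim1", "dim2"))
  structure(list(coords = coords, method = method, params = params,
                 consensus_checksum = attr(scores, "consensus_checksum")),
            class = "embedding_2d")
}
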
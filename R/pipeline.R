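#' @title End-to-end pipeline and run artifacts
#' @name pipeline
#' @description [run_pipeline()] chains normalization, the ICP ensemble,
#'   consensus clustering, K selection, embedding and marker detection, and
#'   writes all artifacts plus a machine-readable manifest to a run
#'   directory.  [recut_run()] re-cuts a saved dendrogram at a new K in
#'   seconds, without recomputing ICP or PCA.
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

# hclust merge table <-> 4-column CSV (left, right, height, size)
.linkage_table <- function(hc) {
  n_leaves <- length(hc$order)
  size <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    left <- hc$merge[i, 1L]
    right <- hc$merge[i, 2L]
    size[i] <- (if (left < 0) 1L else size[left]) +
      (if (right < 0) 1L else size[right])
  }
  data.frame(left = hc$merge[, 1L], right = hc$merge[, 2L],
             height = hc$height, size = size)
}

.linkage_from_table <- function(tab, cell_ids) {
  hc <- list(merge = as.matrix(tab[, c("left", "right")]),
             height = tab$height,
             labels = cell_ids,
             method = "ward.D2",
             order = seq_along(cell_ids))
  dimnames(hc$merge) <- NULL
  class(hc) <- "hclust"
  hc
}

#' Run the full consensus-clustering pipeline
#'
#' Executes, in order: read (if `input` is a path), log-normalization (if
#' `normalize`), the expressed-gene filter, an ensemble of `L` ICP runs,
#' the joint probability matrix, PCA to `p` components, Ward linkage,
#' silhouette selection of K (skipped when `K` is given), the dendrogram
#' cut, an optional 2-D embedding, and optional one-vs-rest marker
#' detection.  All artifacts are written to `out_dir` as plain-text CSV
#' plus a JSON manifest recording every parameter, seed and the package
#' version, so a rerun from the manifest reproduces the labels exactly.
#' Any stage failure aborts with the stage name; nothing is written until
#' every computation has finished.
#'
#' @param input cells x genes matrix, or a path (a directory is read as a
#'   Matrix-Market/10x directory, a file as dense delimited text).
#' @param out_dir run directory to create/populate.
#' @param k,d,C,r,max_epochs ICP parameters, see [icp_params()].
#' @param L number of ICP runs (default 200).
#' @param p number of principal components (default 50).
#' @param K fixed number of consensus clusters (NULL = silhouette
#'   selection over `K_search`).
#' @param K_search candidate K range for the silhouette method.
#' @param seed base seed for the whole run.
#' @param threads worker processes for the ICP ensemble.
#' @param normalize apply [log_normalize()] to the input (set FALSE for
#'   already-normalized input; the pipeline never guesses).
#' @param scale_factor normalization scale factor.
#' @param embedding `"tsne"`, `"umap"` or `"none"`.
#' @param perplexity t-SNE perplexity (reduced automatically only by error,
#'   never silently).
#' @param find_markers run [find_all_gene_markers()] on the final labels.
#' @param filters marker filter settings, see [filter_params()].
#' @return (invisibly) list with labels, scores, eigenvalues, linkage,
#'   silhouette profile, embedding, markers, ensemble summary and the
#'   manifest.
#' @export
run_pipeline <- function(input, out_dir,
                         k = 15L, d = 0.3, C = 0.3, r = 5L,
                         max_epochs = 200L,
                         L = 200L, p = 50L, K = NULL, K_search = 2:50,
                         seed = 1L, threads = 1L,
                         normalize = TRUE, scale_factor = 1e4,
                         embedding = c("tsne", "umap", "none"),
                         perplexity = 30,
                         find_markers = TRUE,
                         filters = filter_params()) {
  embedding <- match.arg(embedding)
  X <- .stage("read", {
    if (is.character(input)) {
      if (dir.exists(input)) read_matrix(input, "mtx_dir")
      else read_matrix(input, "dense_delim")
    } else .validate_expression(input)
  })
  if (normalize) X <- .stage("normalize", log_normalize(X, scale_factor))
  flt <- .stage("gene_filter", apply_gene_filter(X))
  X <- flt$matrix
  params <- icp_params(k = k, d = d, C = C, r = r,
                       max_epochs = max_epochs, seed = seed)
  ensemble <- .stage("icp_ensemble",
                     run_icp_ensemble(X, params, L = L, threads = threads))
  joint <- .stage("joint_matrix", build_joint_matrix(ensemble))
  pca <- .stage("pca", pca_scores(joint, p = p))
  linkage <- .stage("ward_linkage", ward_linkage(pca$scores))
  sil <- NULL
  if (is.null(K)) {
    set.seed(seed)  # silhouette subsampling, if any
    sil <- .stage("select_k",
                  select_k_silhouette(pca$scores, linkage, K_search))
    K <- sil$K_best
  }
  labels <- .stage("cut_tree", cut_tree(linkage, K))
  emb <- NULL
  if (embedding != "none")
    emb <- .stage("embed",
                  embed_cells(pca$scores, method = embedding,
                              perplexity = perplexity, seed = seed))
  markers <- NULL
  if (find_markers)
    markers <- .stage("markers",
                      find_all_gene_markers(X, labels, filters,
                                            seed = seed))
  manifest <- list(
    package = "scICP",
    version = as.character(utils::packageVersion("scICP")),
    parameters = list(k = k, d = d, C = C, r = r, max_epochs = max_epochs,
                      L = L, p = p, K = K,
                      K_search = range(K_search), seed = seed,
                      threads = threads, normalize = normalize,
                      scale_factor = scale_factor, embedding = embedding,
                      perplexity = perplexity,
                      find_markers = find_markers,
                      filters = unclass(filters)),
    run_seeds = vapply(ensemble, function(r) r$seed, integer(1)),
    n_cells = nrow(X), n_genes = ncol(X),
    genes_removed = length(flt$removed))

  .stage("write_outputs", {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(cell_id = rownames(X), cluster = labels),
              file.path(out_dir, "labels.csv"), row.names = FALSE,
              quote = FALSE)
    sc <- data.frame(cell_id = rownames(X), as.matrix(pca$scores),
                     check.names = FALSE)
    write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(.linkage_table(linkage), file.path(out_dir, "linkage.csv"),
              row.names = FALSE, quote = FALSE)
    if (!is.null(sil))
      write.csv(sil$profile, file.path(out_dir, "silhouette_profile.csv"),
                row.names = FALSE, quote = FALSE)
    if (!is.null(emb))
      write.csv(data.frame(cell_id = rownames(emb$coords), emb$coords),
                file.path(out_dir, "embedding.csv"), row.names = FALSE,
                quote = FALSE)
    if (!is.null(markers))
      write.csv(markers, file.path(out_dir, "markers.csv"),
                row.names = FALSE, quote = FALSE)
    writeLines(flt$removed, file.path(out_dir, "removed_genes.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(list(labels = labels, scores = pca$scores,
                 eigenvalues = pca$eigenvalues, linkage = linkage,
                 silhouette = sil, embedding = emb, markers = markers,
                 ensemble = ensemble, manifest = manifest))
}

#' Re-cut a saved consensus dendrogram at a new K
#'
#' Reads `linkage.csv` and `labels.csv` from a previous [run_pipeline()]
#' directory, rebuilds the merge tree, cuts it at `K` and writes
#' `labels_K<K>.csv`.  No ICP or PCA computation is repeated, so this is
#' effectively instantaneous even for large runs.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @param K new number of consensus clusters.
#' @return (invisibly) the new integer label vector, named by cell id.
#' @export
recut_run <- function(run_dir, K) {
  link_path <- file.path(run_dir, "linkage.csv")
  if (!file.exists(link_path))
    stop("no linkage artifact found at ", link_path,
         "; run_pipeline() must be run first")
  tab <- read.delim(link_path, sep = ",")
  cells <- read.delim(file.path(run_dir, "labels.csv"), sep = ",")$cell_id
  hc <- .linkage_from_table(tab, cells)
  labels <- cut_tree(hc, K)
  names(labels) <- cells
  write.csv(data.frame(cell_id = cells, cluster = labels),
            file.path(run_dir, sprintf("labels_K%d.csv", K)),
            row.names = FALSE, quote = FALSE)
  invisible(labels)
}
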
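#' Specification for a synthetic single-cell count dataset
#'
#' Describes a planted-population UMI-like dataset: `K_true` populations in
#' given proportions, a log-normal law for per-gene baseline mean
#' expression, a disjoint set of `markers_per_pop` marker genes per
#' population whose mean is shifted by `2^marker_log2_shift` inside that
#' population, Poisson (optionally negative-binomial) count sampling, and a
#' uniform per-entry dropout (zero-inflation) probability.  Marker genes are
#' given a floor on their baseline mean so that planted markers are
#' detectable genes, as real marker genes are.  The defaults describe the
#' reference validation dataset used throughout the test suite: 500 cells,
#' 2000 genes, 5 equal populations, 20 markers per population with a 4-fold
#' (log2 shift 2) up-shift.
#'
#' @param N number of cells.
#' @param M number of genes.
#' @param K_true number of planted populations.
#' @param proportions length-`K_true` population proportions (default
#'   equal); rare populations down to a few cells are allowed as long as
#'   every population keeps >= 2 cells.
#' @param markers_per_pop marker genes planted per population (disjoint
#'   across populations).
#' @param marker_log2_shift log2 of the in-population mean multiplier for
#'   marker genes (may be negative for down-shifted markers).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean.
#' @param marker_baseline_floor minimum baseline mean for marker genes.
#' @param dropout per-gene-per-cell zero-inflation probability.
#' @param dispersion optional negative-binomial dispersion (NULL = Poisson;
#'   otherwise counts are NB with `size = 1/dispersion`).
#' @param seed integer seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(N = 500L, M = 2000L, K_true = 5L, proportions = NULL,
                     markers_per_pop = 20L, marker_log2_shift = 2,
                     baseline_meanlog = -2, baseline_sdlog = 1.5,
                     marker_baseline_floor = 1, dropout = 0.2,
                     dispersion = NULL, seed = 1L) {
  if (is.null(proportions)) proportions <- rep(1 / K_true, K_true)
  stopifnot(length(proportions) == K_true, all(proportions > 0),
            abs(sum(proportions) - 1) < 1e-8,
            markers_per_pop >= 0, K_true * markers_per_pop <= M,
            dropout >= 0, dropout < 1, N >= 2, M >= 1, K_true >= 1)
  if (floor(N * min(proportions)) < 2)
    stop("smallest population would have fewer than 2 cells")
  structure(list(N = as.integer(N), M = as.integer(M),
                 K_true = as.integer(K_true), proportions = proportions,
                 markers_per_pop = as.integer(markers_per_pop),
                 marker_log2_shift = marker_log2_shift,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 marker_baseline_floor = marker_baseline_floor,
                 dropout = dropout, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Largest-remainder apportionment of N cells to the population proportions.
.apportion <- function(N, proportions) {
  raw <- N * proportions
  sizes <- floor(raw)
  short <- N - sum(sizes)
  if (short > 0) {
    order_frac <- order(raw - sizes, decreasing = TRUE)
    sizes[order_frac[seq_len(short)]] <- sizes[order_frac[seq_len(short)]] + 1
  }
  as.integer(sizes)
}

#' Simulate planted-population UMI counts
#'
#' Draws counts per the [sim_spec()] generative model: each gene's mean in a
#' cell is its baseline mean times `2^marker_log2_shift` if the gene is a
#' marker of the cell's population; counts are Poisson (or
#' negative-binomial) draws, then zeroed independently with the dropout
#' probability.  Cells are ordered by population.
#'
#' @param spec a [sim_spec()] object.
#' @return list with `counts` (sparse cells x genes integer matrix),
#'   `truth` (integer population labels) and `marker_map` (named list:
#'   population -> character vector of marker gene ids).
#' @export
simulate_counts <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  sizes <- .apportion(spec$N, spec$proportions)
  if (any(sizes < 2)) stop("infeasible spec: population with < 2 cells")
  truth <- rep(seq_len(spec$K_true), sizes)
  gene_ids <- sprintf("gene_%04d", seq_len(spec$M))
  cell_ids <- sprintf("cell_%04d", seq_len(spec$N))
  baseline <- rlnorm(spec$M, spec$baseline_meanlog, spec$baseline_sdlog)
  n_markers <- spec$K_true * spec$markers_per_pop
  marker_idx <- if (n_markers > 0) sample.int(spec$M, n_markers)
                else integer(0)
  baseline[marker_idx] <- pmax(baseline[marker_idx],
                               spec$marker_baseline_floor)
  marker_map <- if (spec$markers_per_pop > 0) {
    split(gene_ids[marker_idx],
          rep(seq_len(spec$K_true), each = spec$markers_per_pop))
  } else {
    rep(list(character(0)), spec$K_true)
  }
  names(marker_map) <- as.character(seq_len(spec$K_true))
  blocks <- lapply(seq_len(spec$K_true), function(pop) {
    lam <- baseline
    pop_markers <- marker_idx[(pop - 1L) * spec$markers_per_pop +
                                seq_len(spec$markers_per_pop)]
    lam[pop_markers] <- lam[pop_markers] * 2^spec$marker_log2_shift
    n <- sizes[pop]
    counts <- if (is.null(spec$dispersion)) {
      matrix(rpois(n * spec$M, rep(lam, each = n)), nrow = n)
    } else {
      matrix(rnbinom(n * spec$M, mu = rep(lam, each = n),
                     size = 1 / spec$dispersion), nrow = n)
    }
    if (spec$dropout > 0)
      counts[matrix(runif(n * spec$M) < spec$dropout, nrow = n)] <- 0L
    counts
  })
  counts <- do.call(rbind, blocks)
  dimnames(counts) <- list(cell_ids, gene_ids)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "generalMatrix")
  list(counts = counts, truth = truth, marker_map = marker_map)
}

#' Write a simulated dataset as an on-disk fixture
#'
#' Writes the counts in one of the formats [read_matrix()] accepts, plus
#' `truth.csv` (cell_id, population) and `marker_map.csv` (population,
#' gene_id).
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory.
#' @param format matrix format, as in [write_matrix()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir, format = c("mtx_dir", "dense_delim")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx_dir") {
    write_matrix(sim$counts, dir, "mtx_dir")
  } else {
    write_matrix(sim$counts, file.path(dir, "counts.tsv"), "dense_delim")
  }
  write.csv(data.frame(cell_id = rownames(sim$counts),
                       population = sim$truth),
            file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  mm <- data.frame(
    population = rep(names(sim$marker_map),
                     lengths(sim$marker_map)),
    gene_id = unlist(sim$marker_map, use.names = FALSE))
  write.csv(mm, file.path(dir, "marker_map.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
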
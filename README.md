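# scICP

Cell population identification for single-cell RNA-seq by **iterative
clustering projection (ICP)** and consensus clustering.

Unsupervised clustering of scRNA-seq data usually starts by selecting a
few thousand highly variable genes, which can discard exactly the genes
that distinguish subtle subpopulations.  ICP takes a different route: it
searches for a partition `S` of the cells that is maximally
*self-predictable*,

```
argmax_S  ARI(S, S'),
```

where `S'` is the projection of `S` through a one-vs-rest L1-regularized
logistic-regression classifier (objective
`min_w ||w||_1 + C * sum_i log(1 + exp(-y_i w' x_i))`) trained on a
class-balanced subsample (`n = ceiling(N d / k)` cells per cluster) and
applied back to all cells, and ARI is the adjusted Rand index.  The L1
penalty performs gene selection implicitly at every epoch, so no
highly-variable-gene preselection is needed.  Each run yields an N x k
matrix of cluster-membership probabilities; `L` independent runs are
concatenated, reduced to `p` principal components, and clustered with
Ward's method.  The number of consensus clusters `K` is chosen by the
silhouette method (or fixed by the user), markers are scored per cluster
with Wilcoxon rank-sum tests and Bonferroni correction, and the
consensus space is embedded in 2-D with t-SNE or UMAP.

The package is aimed at analysts who want high-resolution, reproducible
cluster structure with per-cell membership probabilities and built-in
marker reports, and at methodologists who want a fully scripted,
deterministic reimplementation of the ICP + consensus approach with a
synthetic-data generator for validation.

## Worked example

```r
library(scICP)

# a planted five-population dataset: 500 cells x 2000 genes,
# 20 four-fold marker genes per population
sim <- simulate_counts(sim_spec(seed = 1))
res <- run_pipeline(sim$counts, "demo_run",
                    L = 10, K = 5, seed = 1,
                    embedding = "none", find_markers = TRUE)
table(res$labels)
head(res$markers[, c("gene_id", "cluster_id", "log2fc", "adj_p_value")], 3)
```

```
#>   1   2   3   4   5
#> 268  37  70  90  35

#>     gene_id cluster_id     log2fc  adj_p_value
#> 1 gene_1295          1  0.6253476 1.770508e-06
#> 2 gene_1841          1  0.5082370 1.481886e-04
#> 3 gene_1804          1 -0.4978040 4.729086e-01
```

The cluster sizes show a property discussed at length in the methods
vignette: on synthetic data whose populations differ in only a small
marker panel, the self-projection loop finds stable structure in the
noise realization rather than the planted populations, so the consensus
labels need not match the planted truth (marker detection against known
labels, by contrast, is exact — see `scripts/acceptance.R` output).

The run directory (`demo_run/`) now contains `labels.csv` (cell,
cluster), `scores.csv` (consensus PCA scores), `linkage.csv` (the Ward
merge tree), `markers.csv`, `removed_genes.txt` and `manifest.json`
(all parameters, seeds and the package version).  Because the dendrogram
is saved, changing the number of clusters afterwards is instant:

```r
recut_run("demo_run", K = 8)   # writes labels_K8.csv in seconds
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/scicp.R` with `simulate`, `run` and `recut` subcommands.

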
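# tdfe — tensor-decomposition-based unsupervised feature extraction for single-cell multiomics

Single-cell assays that jointly measure gene expression, DNA methylation
and chromatin accessibility (scChaRM-seq, scNMT-seq) produce matrices
with tens of millions of genomic features of which only a few percent
are ever observed in any given cell. Most integration methods either
impute the missing values or pre-filter the features; both steps inject
arbitrariness. `tdfe` integrates the three layers without doing either:
missingness stays encoded as exact zeros in sparse matrices, and all
layers enter one joint decomposition.

## Method

For each omics layer *k*, a sparse feature-by-cell matrix
x<sub>ijk</sub> ∈ R<sup>N_k × M</sup> is built:

* **expression** — raw counts, then per-cell centering and scaling so
  that Σ<sub>i</sub> x<sub>ij1</sub> = 0 and
  Σ<sub>i</sub> x<sub>ij1</sub>² = N₁;
* **methylation** — the union of observed sites, ternary-encoded
  (+1 methylated, −1 unmethylated, 0 unobserved);
* **accessibility** — signal summed into fixed 200-nt "nucleosome
  region" bins.

Optionally the site-level layers are L1-normalized per cell
(Σ<sub>i</sub>|x<sub>ijk</sub>| = N_k); for datasets where some cells
carry very few observations this normalization is skipped because it
would give those cells enormous weight.

Each layer is reduced to a common rank *L* (default 10) by truncated
SVD, x<sub>ijk</sub> = Σ<sub>ℓ</sub> λ<sub>ℓ</sub> u<sub>ℓik</sub>
v<sub>ℓjk</sub>, and projected onto its left singular vectors,
x<sub>ℓjk</sub> = Σ<sub>i</sub> u<sub>ℓik</sub> x<sub>ijk</sub>. The
projections are stacked into an L × M × K tensor over the cells shared
by all layers and decomposed by higher-order SVD:

x<sub>ℓjk</sub> = Σ G(ℓ₁,ℓ₂,ℓ₃) u<sub>ℓ₁ℓ</sub> u<sub>ℓ₂j</sub> u<sub>ℓ₃k</sub>

Cell-mode singular vectors u<sub>ℓ₂j</sub> are tested against a known
cell classification by categorical regression (one-way OLS F-test),
with Benjamini–Hochberg correction; components with adjusted p < 0.01
are "coincident" with the classification. Feature-mode components ℓ₁
are ranked by their core energy over the coincident ℓ₂,
Σ<sub>ℓ₂ sel</sub> Σ<sub>ℓ₃</sub> G²(ℓ₁,ℓ₂,ℓ₃); the top component is
back-projected to genes, u<sub>ℓ₁i</sub> = Σ<sub>ℓ</sub> u<sub>ℓ₁ℓ</sub>
u<sub>ℓi1</sub>, and genes get χ² p-values from
P<sub>i</sub> = P<sub>χ²</sub>[> Σ<sub>ℓ₁</sub>(u<sub>ℓ₁i</sub>/σ<sub>ℓ₁</sub>)²],
BH-corrected, selected at adjusted P < 0.01. Cells are embedded in 2-D
with UMAP (n_neighbors = 100) on all cell-mode columns.

## Worked example

The package ships a synthetic trimodal generator with planted
trajectory-stage structure (300 cells, 3 stages; 2,000 genes of which
50 are stage markers; 50,000 methylation sites; 50,000 accessibility
sites; sparsity 0.28 / 0.03 / 0.05):

```r
library(tdfe)
sim <- simulate_multiomics(simulation_spec(seed = 42))
res <- run_pipeline(sim$expression, sim$methylation, sim$accessibility,
                    labels = sim$labels, normalization = "dataset2",
                    seed = 42)
res
#> <td_fe> integration of 3 layers ( expression, methylation, accessibility ) over 300 shared cells
#> coincident cell-mode vectors: 4 of 30 at alpha = 0.01
#> selected features: 44 of 2000
glance(res)
#> # A tibble: 1 x 7
#>   n_cells n_layers     L n_cell_vectors n_coincident n_selected_features alpha
#> 1     300        3    10             30            4                  44  0.01
head(dplyr::filter(tidy(res), selected), 3)
#> # A tibble: 3 x 6
#>   feature_id loading_1  p.value adj.p.value selected statistic
#> 1 gene1716       0.241 4.59e-27    9.17e-24 TRUE         116.
#> 2 gene0354       0.218 1.57e-22    1.57e-19 TRUE          95.4
#> 3 gene0132       0.211 3.49e-21    2.33e-18 TRUE          89.2
```

Four of the thirty cell-mode HOSVD vectors coincide with the stage
labels; the χ² selection recovers 44 genes, 41 of them among the 50
planted markers. The UMAP of all 30 cell-mode columns separates the
stages (mean silhouette 0.133 against −0.04 for the
methylation+accessibility-only integration):

```r
ggplot2::autoplot(res$embedding, labels = sim$labels)
embedding_silhouette(res$embedding, sim$labels)
#> [1] 0.133
```

A thin command-line interface wraps the same functions
(`inst/cli/tdfe.R`; subcommands `simulate`, `ingest`, `normalize`,
`reduce`, `hosvd`, `associate`, `select`, `embed`, `run`).

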
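---
title: "Tensor-decomposition feature extraction for single-cell multiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor-decomposition feature extraction for single-cell multiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfe)
```

## The problem

Trimodal single-cell assays measure gene expression together with DNA
methylation and chromatin accessibility in the same cells. The
site-level layers are enormous (tens of millions of genomic positions)
and extremely sparse: only a few percent of (site, cell) pairs are ever
observed. Imputing the missing values densifies matrices that cannot be
held in memory, and pre-filtering features injects arbitrary choices.
`tdfe` implements a route that needs neither: missingness is encoded as
exact zeros, every layer is reduced by a truncated SVD that operates on
sparse storage, and the reduced layers are integrated by a higher-order
SVD (HOSVD) whose layer-mode factor decides the relative weight of each
omics automatically.

## Pipeline and model

1. **Ingestion.** Expression arrives as a genes-by-cells count TSV.
   Methylation arrives as per-cell site observations; the feature set
   is the union of sites observed in at least one cell, and each
   observed (site, cell) pair is encoded +1 (level at or above the call
   threshold, default 0.5) or −1, with 0 for "not observed". The
   ternary code makes missingness a neutral value: an unobserved site
   pulls no component in any direction. Accessibility arrives as
   per-cell site observations summed into half-open 200-nt bins —
   roughly one nucleosome (147 nt wrapped plus linker) — so the feature
   is "signal in this nucleosome-scale window". Coordinates are 0-based
   internally; 1-based input positions are converted on read.

2. **Normalization.** Expression is centered and scaled per cell
   (sum 0, sum of squares N). Site-level layers are either
   L1-normalized per cell (every cell gets total absolute mass N_k,
   mode `"dataset1"`) or left raw (mode `"dataset2"`). The raw mode
   exists because cells with very few observations would otherwise be
   rescaled by huge factors and dominate the decomposition; it is the
   right choice for scNMT-style data and for this package's synthetic
   fixtures, which emulate that dialect.

3. **Rank reduction.** Each layer is truncated-SVD'd to a common rank
   L (default 10) and projected onto its left singular vectors, giving
   an L × M matrix per layer over the shared cells; the layers stack
   into an L × M × K tensor. Cells missing from any layer are dropped,
   never imputed.

4. **HOSVD.** Factor matrices are left singular vectors of the mode-n
   unfoldings (mode n on rows, remaining modes in ascending order on
   columns, first remaining mode fastest); the core is the tensor
   contracted with the factor transposes. The cell-mode unfolding is
   M × (L·K) with rank at most L·K, so only M′ = min(M, L·K) cell-mode
   columns are computed — columns beyond the unfolding rank are not
   unique and are never consumed downstream.

5. **Association.** Every cell-mode column is regressed on the class
   labels (OLS with intercept and class indicators; the F-test on
   (S−1, M−S) degrees of freedom is invariant to the dummy coding).
   The family of raw p-values from one analysis run is BH-adjusted
   jointly; adjusted p < α (default 0.01) marks a component
   "coincident" with the classification. A zero-variance component is
   assigned p = 1 by convention rather than NaN, so constant vectors
   are never selected.

6. **Gene selection.** Feature-mode components are ranked by their
   squared core mass over the coincident cell-mode components and all
   layers; the top component (configurable, default 1 — only the
   top-ranked component is used) is back-projected through the
   expression layer's left singular vectors to native genes. Under the
   null that a gene's loading is Gaussian with per-component scale
   σ_ℓ₁, the summed squared standardized loadings are χ² with as many
   degrees of freedom as components used; upper-tail p-values are
   BH-adjusted and genes selected at adjusted P < α. The default σ_ℓ₁
   is the sample standard deviation of the back-projected loadings
   (denominator N−1); a zero-mean variant √mean(u²) is available via
   `center = FALSE`, since the null is a mean-zero Gaussian. With tail
   signal present the centered estimate is slightly the larger, making
   the default the more conservative choice.

7. **Embedding.** UMAP on all M′ cell-mode columns (not only the
   coincident ones), `n_neighbors = 100`, all other hyperparameters at
   the library defaults, single-threaded and seeded so coordinates are
   reproducible.

## Numerical choices

* **Truncated SVD.** For every realistic single-cell shape the cell
  count is a few hundred to a few thousand while features run to 10⁷,
  so the decomposition is computed exactly from the eigendecomposition
  of the small Gram matrix (crossprod on sparse storage; no dense
  feature-by-cell array is ever formed). This is deterministic and
  needs no convergence control. When both dimensions exceed 4096 the
  package switches to seeded Lanczos bidiagonalization (`irlba`,
  tolerance 1e−8, iteration cap 1000). Singular values below
  1e−12 × λ₁ indicate rank deficiency; their left-factor columns are
  replaced by an orthonormal completion.
* **Sign convention.** Singular vectors are sign-ambiguous, so each
  (u, v) pair is flipped to make the largest-magnitude entry of u
  positive (ties: first index). The same rule applies to HOSVD factor
  columns. This makes runs bit-reproducible.
* **Degenerate spectra.** If the singular value at the truncation
  boundary is within 1e−10 (relative) of the next one, the kept
  subspace is not unique; the package warns and continues.
* **Tolerances.** Normalization post-conditions hold to 1e−10
  (relative); HOSVD reconstructs to better than 1e−8 relative
  Frobenius error. These follow from double-precision accumulation
  over at most ~10⁷ entries.
* **Ties in ranking.** Core-energy ties between feature-mode
  components break toward the smaller index.

## What the synthetic generator emulates

`simulation_spec()` describes a 300-cell, 3-class trimodal dataset
with 2,000 genes, 50,000 methylation sites and 50,000 accessibility
sites, with nonzero fractions 0.28 / 0.03 / 0.05 — the sparsity regime
of real scChaRM/scNMT data. The classes model ordered stages of a
developmental trajectory, the typical origin of single-cell multiomics
classifications, and the generator is built so that class structure
dominates each layer's variance — the situation in which this method
is used, where real classifications coincide with most leading
singular vectors:

* **Expression**: negative-binomial counts (size 2) with log-normal
  baseline means; entries are thinned to the target nonzero fraction.
  Fifty planted marker genes follow μ·(1 + a·z_s), linear in the
  centered stage score z, with signed amplitude a = ±effect (capped at
  2 = fully on/off across the trajectory). Markers draw their
  baselines from a high-expression distribution because canonical
  stage markers are reliably detectable genes, not members of the
  low-count bulk. Amplitudes are adjusted so both the expected
  per-class total and its projection on the baseline profile are
  class-independent: regulation redistributes transcriptome share;
  per-cell yield is a technical property.
* **Methylation**: per-(site, cell) Bernoulli observation (p = 0.03),
  binary calls with bimodal Beta baselines; 2,500 differentially
  methylated sites sweep from hypo- to hypermethylated (or back) along
  the trajectory on the logit scale, with a per-class offset chosen so
  the expected global methylated fraction is class-independent.
* **Accessibility**: one site per 200-nt bin, positive Poisson counts;
  2,500 planted bins scale their rates linearly with the stage score,
  amplitudes centered so expected total signal is class-independent.

Per-cell site tables are emitted in exactly the on-disk dialect the
readers ingest, and the generator builds its matrices through the same
ingestion functions, so simulations exercise the union/ternary/binning
code paths end to end. Synthetic analyses run with
`normalization = "dataset2"` to match the dialect being emulated.

What the generator does **not** model: chemistry-specific biases
(bisulfite conversion, GpC enzyme efficiency), genomic covariates (CpG
density, replication timing), doublets, batch effects, or continuous
pseudotime within a stage. Passing tests therefore demonstrate that the
pipeline recovers planted low-rank class structure under realistic
sparsity — not that it overcomes assay-specific artifacts.

Problem sizes used by the test-suite: unit tests run a reduced
configuration (90 cells, 400 genes, 4,000 sites per layer); the
acceptance checks run the full study-scale defaults above, with 100
replicate seeds for the no-signal control and 10 seeds for the
recovery and embedding comparisons.

## Design decisions that were genuinely open

* **Methylation call threshold**: nothing in the data dictates how a
  fractional methylation level maps to a call; the package uses
  level ≥ 0.5 ⇒ methylated, exposed as `call_threshold`.
* **Bin boundary**: bins are half-open [start, start + 200), so a site
  at position 200 belongs to the second bin. With 0-based coordinates
  the arithmetic is `pos %/% bin_size`.
* **σ_ℓ₁ estimation** (centered vs zero-mean): both implemented,
  centered is the default (see above).
* **Cell-mode family size**: the BH family is all cell-mode vectors of
  one analysis (per-layer SVD: L of them; HOSVD: M′ = min(M, K·L)),
  never pooled across analyses.
* **Layers to integrate**: any subset of at least two layers can be
  stacked; gene selection targets the expression layer by default but
  the back-projection is layer-generic.

## Known limitations

* The gene-selection route uses a single top-ranked feature-mode
  component by default; class geometries spread over several
  components (for example many unordered classes) need `top_l1 > 1`.
* The χ² null treats loadings as independent Gaussians; with a large
  planted fraction the scale estimate inflates and selection becomes
  conservative.
* L1 normalization of site-level layers amplifies cells with few
  observations; use `"dataset2"` mode for sparse-coverage designs.
* UMAP coordinates are reproducible per seed but not comparable across
  seeds; only label-separation summaries (silhouettes) are.
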
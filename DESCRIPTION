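Package: tdfe
Title: Tensor-Decomposition-Based Unsupervised Feature Extraction for
    Single-Cell Multiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates single-cell multiomics layers (gene expression,
    ternary-encoded DNA methylation, and DNA accessibility summed into
    fixed 200-nt genomic bins) without imputing missing values. Each
    sparse feature-by-cell layer is reduced to a common rank by truncated
    singular value decomposition, the reduced layers are stacked into a
    rank-by-cell-by-layer tensor and decomposed by higher-order SVD
    (HOSVD). Cell-mode singular vectors coincident with a known cell
    classification are identified by categorical regression with
    Benjamini-Hochberg correction, genes are selected by back-projecting
    core-energy-ranked feature-mode components and attributing chi-squared
    p-values, and cells are embedded in two dimensions with UMAP. Includes
    a synthetic multiomics generator with planted class structure for
    end-to-end validation, and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    irlba,
    uwot,
    stats,
    utils,
    methods,
    tibble,
    generics
Suggests:
    testthat (>= 3.0.0),
    cluster,
    ggplot2,
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
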
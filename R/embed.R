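#' Two-dimensional UMAP embedding of cell-mode factors
#'
#' Embeds the cells from their cell-mode singular vectors (all columns,
#' coincident or not) with UMAP. Following the wide-neighborhood setting
#' used for these data, `n_neighbors` defaults to 100; every other UMAP
#' hyperparameter stays at the library default. The run is
#' single-threaded and seeded, so coordinates are reproducible for a
#' fixed seed and input.
#'
#' @param factors numeric matrix, cells in rows (e.g.
#'   `td_hosvd$mode2_factors`), at least 2 columns.
#' @param n_neighbors neighborhood size; must be smaller than the
#'   number of cells. Default 100.
#' @param seed integer seed.
#' @return An `M x 2` matrix of coordinates with the input rownames,
#'   columns `UMAP1`, `UMAP2`; class `td_embedding`.
#' @export
embed_cells <- function(factors, n_neighbors = 100L, seed = 1L) {
  factors <- as.matrix(factors)
  if (ncol(factors) < 2) stop("need at least 2 factor columns to embed")
  if (nrow(factors) <= n_neighbors)
    stop("n_neighbors (", n_neighbors, ") must be smaller than the number ",
         "of cells (", nrow(factors), "); pass a smaller n_neighbors")
  set.seed(seed)
  coords <- uwot::umap(factors, n_neighbors = n_neighbors, n_components = 2,
                       n_threads = 1, n_sgd_threads = 0)
  if (any(!is.finite(coords))) stop("UMAP produced non-finite coordinates")
  dimnames(coords) <- list(rownames(factors), c("UMAP1", "UMAP2"))
  class(coords) <- c("td_embedding", class(coords))
  coords
}

#' Export an embedding with class labels to TSV
#'
#' Writes `cell_id`, `x`, `y`, `class` as tab-separated values, one row
#' per cell. Errors if any embedded cell lacks a label.
#'
#' @param coords an `M x 2` coordinate matrix with cell ids as rownames
#'   (e.g. from [embed_cells()]).
#' @param labels a [class_labels()] object covering the embedded cells.
#' @param path output TSV path.
#' @return The exported data frame, invisibly.
#' @export
export_embedding <- function(coords, labels, path) {
  coords <- unclass(coords)
  if (is.null(rownames(coords)))
    stop("coordinates must carry cell ids as rownames")
  lab <- align_labels(labels, rownames(coords))
  df <- data.frame(cell_id = rownames(coords),
                   x = coords[, 1], y = coords[, 2],
                   class = as.character(lab), row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Mean silhouette width of an embedding by class
#'
#' Summarizes how well the 2-D coordinates separate the known classes:
#' the mean silhouette width over cells, with Euclidean distances on
#' the embedding.
#'
#' @param coords `M x 2` coordinates.
#' @param labels a [class_labels()] object or factor aligned with the
#'   rows (matched by rowname when possible).
#' @return A single number in \[-1, 1\].
#' @export
embedding_silhouette <- function(coords, labels) {
  if (!requireNamespace("cluster", quietly = TRUE))
    stop("the 'cluster' package is required for silhouette computation")
  coords <- unclass(coords)
  g <- if (inherits(labels, "class_labels") && !is.null(rownames(coords)))
    align_labels(labels, rownames(coords)) else
    droplevels(if (inherits(labels, "class_labels")) labels$label
               else factor(labels))
  sil <- cluster::silhouette(as.integer(g), stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Scatter plot of an embedding colored by class
#'
#' @param object a `td_embedding` from [embed_cells()].
#' @param labels optional [class_labels()] or factor for coloring.
#' @param ... ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.td_embedding <- function(object, labels = NULL, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the 'ggplot2' package is required for plotting")
  coords <- unclass(object)
  df <- data.frame(UMAP1 = coords[, 1], UMAP2 = coords[, 2])
  if (!is.null(labels)) {
    df$class <- if (inherits(labels, "class_labels") &&
                    !is.null(rownames(coords)))
      align_labels(labels, rownames(coords)) else factor(labels)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$UMAP1, .data$UMAP2,
                                          colour = .data$class))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$UMAP1, .data$UMAP2))
  }
  p + ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::theme_minimal()
}
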
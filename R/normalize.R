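#' Per-cell L1 normalization of a sparse omics layer
#'
#' Rescales every cell (column) so that the sum of absolute values over
#' the N features equals N. Cells with very few observations would
#' otherwise contribute tiny column norms and, after rank reduction,
#' receive disproportionate weight; equalizing the L1 mass puts all
#' cells on the same footing while leaving the sparsity pattern
#' untouched (zeros stay zero).
#'
#' @param x an [omics_matrix()] (any kind). Methylation output is no
#'   longer ternary, so the result is returned as a plain rescaled
#'   matrix wrapped in the same class with kind preserved.
#' @return An object like `x` with every column satisfying
#'   `sum(abs(column)) == nrow(x)` to within numerical precision.
#' @export
normalize_l1 <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  l1 <- Matrix::colSums(abs(v))
  zero <- which(l1 == 0)
  if (length(zero))
    stop("cannot L1-normalize all-zero cell(s): ",
         paste(utils::head(cell_ids(x)[zero], 5), collapse = ", "))
  scaled <- v %*% Matrix::Diagonal(ncol(v), nrow(v) / l1)
  scaled <- methods::as(methods::as(scaled, "generalMatrix"), "CsparseMatrix")
  dimnames(scaled) <- dimnames(v)
  out <- x
  out$values <- scaled
  out
}

#' Per-cell centering and scaling of an expression layer
#'
#' Standardizes each cell (column) over the N features so that the
#' entries sum to zero and their squares sum to N. Centering destroys
#' sparsity, so the result is a dense base matrix; this is intended for
#' the expression layer, whose feature count is small relative to the
#' site-level layers.
#'
#' @param x an [omics_matrix()] or a dense feature-by-cell matrix with
#'   dimnames.
#' @return A dense numeric matrix with feature/cell dimnames; per column
#'   `sum(col) == 0` and `sum(col^2) == nrow` within numerical precision.
#' @export
normalize_center_scale <- function(x) {
  m <- if (inherits(x, "omics_matrix")) as.matrix(x$values) else as.matrix(x)
  n <- nrow(m)
  centered <- sweep(m, 2, colMeans(m))
  ss <- colSums(centered^2)
  zero <- which(ss == 0)
  if (length(zero))
    stop("cannot center-scale constant cell(s): ",
         paste(utils::head(colnames(m)[zero], 5), collapse = ", "))
  sweep(centered, 2, sqrt(ss / n), "/")
}

#' Per-layer normalization plan
#'
#' Returns which normalization to apply to each layer before SVD.
#' `"dataset1"` (scChaRM-seq style, cells with ample site coverage)
#' L1-normalizes methylation and accessibility; `"dataset2"` (scNMT-seq
#' style, where some cells carry very few observations and L1 rescaling
#' would blow their weight up) leaves them untouched. Expression is
#' centered and scaled in both. `"custom"` takes explicit choices.
#'
#' @param dataset_mode one of `"dataset1"`, `"dataset2"`, `"custom"`.
#' @param expression,methylation,accessibility for `"custom"`: one of
#'   `"center_scale"`, `"l1"`, `"none"` per layer.
#' @return Named character vector: normalization per layer.
#' @export
normalization_plan <- function(dataset_mode = c("dataset1", "dataset2", "custom"),
                               expression = "center_scale",
                               methylation = "none",
                               accessibility = "none") {
  dataset_mode <- match.arg(dataset_mode)
  plan <- switch(dataset_mode,
    dataset1 = c(expression = "center_scale", methylation = "l1",
                 accessibility = "l1"),
    dataset2 = c(expression = "center_scale", methylation = "none",
                 accessibility = "none"),
    custom   = c(expression = expression, methylation = methylation,
                 accessibility = accessibility))
  ok <- c("center_scale", "l1", "none")
  if (!all(plan %in% ok))
    stop("unknown normalization(s): ", paste(setdiff(plan, ok), collapse = ", "))
  plan
}

#' Apply one normalization choice to a layer
#'
#' @param x an [omics_matrix()].
#' @param method `"center_scale"`, `"l1"` or `"none"`.
#' @return The normalized layer: an `omics_matrix` for `"l1"`/`"none"`,
#'   a dense matrix for `"center_scale"`.
#' @export
apply_normalization <- function(x, method) {
  switch(method,
         center_scale = normalize_center_scale(x),
         l1 = normalize_l1(x),
         none = x,
         stop("unknown normalization: ", method))
}
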
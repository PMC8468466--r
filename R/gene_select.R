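#' Back-project a feature-mode HOSVD component onto original features
#'
#' Converts a component living in the reduced L-space back to the
#' native features of one layer through that layer's left singular
#' vectors: `u_{l1,i} = sum_l U1[l, l1] * u[i, l]`, i.e. the layer's
#' `u` matrix times column `l1` of the feature-mode factor. With an
#' identity feature-mode factor this returns the layer's own `l1`-th
#' left singular vector.
#'
#' @param mode1_factors `L x L` feature-mode factor matrix
#'   (`td_hosvd$mode1_factors`), columns indexing components.
#' @param feature_left_vectors `N x L` left singular vectors of the
#'   layer (`td_svd$u`).
#' @param l1 component index (may be a vector to back-project several
#'   components at once).
#' @return Numeric vector of length N (or `N x length(l1)` matrix),
#'   named by feature when the left vectors carry rownames.
#' @export
backproject <- function(mode1_factors, feature_left_vectors, l1) {
  mode1_factors <- as.matrix(mode1_factors)
  u <- as.matrix(feature_left_vectors)
  if (ncol(u) != nrow(mode1_factors))
    stop("dimension mismatch: left vectors have ", ncol(u),
         " columns, feature-mode factor has ", nrow(mode1_factors), " rows")
  l1 <- as.integer(l1)
  if (any(l1 < 1 | l1 > ncol(mode1_factors)))
    stop("l1 out of range 1..", ncol(mode1_factors))
  out <- u %*% mode1_factors[, l1, drop = FALSE]
  colnames(out) <- paste0("l1_", l1)
  if (length(l1) == 1) stats::setNames(drop(out), rownames(u)) else out
}

#' Chi-squared p-values for back-projected feature loadings
#'
#' Under the null that the loadings of uninformative features are
#' independently Gaussian with standard deviation `sigma_l1` per
#' component, the statistic `sum_{l1} (u_{l1,i} / sigma_{l1})^2` follows
#' a chi-squared distribution with as many degrees of freedom as there
#' are selected components; `P_i` is its upper-tail probability.
#'
#' @param loadings numeric matrix, features in rows, one column per
#'   selected feature-mode component (a vector is treated as one
#'   column).
#' @param scales `"estimate"` (default) to use each column's sample
#'   standard deviation, or a positive numeric vector of per-column
#'   scales. `center = FALSE` switches the estimate to the zero-mean
#'   form `sqrt(mean(u^2))`, matching the mean-zero Gaussian null.
#' @param center logical; see `scales`.
#' @return A list with `statistic` (per feature), `p.value`, `scales`,
#'   and `df`.
#' @export
chi2_pvalues <- function(loadings, scales = "estimate", center = TRUE) {
  u <- as.matrix(loadings)
  if (!ncol(u)) stop("need at least one selected component")
  if (identical(scales, "estimate")) {
    scales <- if (center) apply(u, 2, stats::sd)
              else sqrt(colMeans(u^2))
  }
  scales <- as.numeric(scales)
  if (length(scales) != ncol(u))
    stop("need one scale per loading column")
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("scales must be positive (zero estimated standard deviation?)")
  stat <- rowSums(sweep(u, 2, scales, "/")^2)
  p <- stats::pchisq(stat, df = ncol(u), lower.tail = FALSE)
  list(statistic = stats::setNames(stat, rownames(u)), p.value = p,
       scales = scales, df = ncol(u))
}

#' Select features by BH-adjusted chi-squared p-values
#'
#' Adjusts the raw feature p-values with Benjamini-Hochberg and flags
#' features whose adjusted p falls below `alpha`.
#'
#' @param raw_p numeric vector of per-feature p-values, named by
#'   feature id when available.
#' @param alpha adjusted-p threshold; default 0.01.
#' @param feature_ids optional feature identifiers (overrides names).
#' @param statistic optional per-feature chi-squared statistic to carry
#'   into the result.
#' @param loadings optional per-feature loading matrix to carry along.
#' @return A tibble of class `td_genes`: `feature_id`, optional
#'   loadings/statistic columns, `p.value`, `adj.p.value`, `selected`,
#'   ordered by adjusted p then feature id.
#' @export
select_features <- function(raw_p, alpha = 0.01, feature_ids = NULL,
                            statistic = NULL, loadings = NULL) {
  if (is.null(feature_ids))
    feature_ids <- if (!is.null(names(raw_p))) names(raw_p)
                   else paste0("feature_", seq_along(raw_p))
  adj <- bh_adjust(raw_p)
  out <- tibble::tibble(feature_id = feature_ids,
                        p.value = as.numeric(raw_p),
                        adj.p.value = adj,
                        selected = adj < alpha)
  if (!is.null(statistic)) out$statistic <- as.numeric(statistic)
  if (!is.null(loadings)) {
    lo <- as.matrix(loadings)
    colnames(lo) <- colnames(lo) %||% paste0("loading_", seq_len(ncol(lo)))
    out <- tibble::add_column(out, tibble::as_tibble(lo), .after = "feature_id")
  }
  out <- out[order(out$adj.p.value, out$feature_id), ]
  attr(out, "alpha") <- alpha
  class(out) <- c("td_genes", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a selected-feature list for external enrichment tools
#'
#' @param x a `td_genes` tibble from [select_features()].
#' @param path output file; one selected feature id per line.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "td_genes"))
  writeLines(x$feature_id[x$selected], path)
  invisible(path)
}
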
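#' Truncated singular value decomposition of one omics layer
#'
#' Computes the top `L` singular triplets of a (possibly very sparse)
#' feature-by-cell matrix without ever forming a dense feature-by-cell
#' array. When the smaller dimension is modest (the usual single-cell
#' situation: a few hundred to a few thousand cells against up to tens
#' of millions of sites) the decomposition is obtained exactly from the
#' eigendecomposition of the small Gram matrix; when both dimensions are
#' large it falls back to seeded Lanczos bidiagonalization
#' ([irlba::irlba()]).
#'
#' Singular vectors are sign-ambiguous; for reproducibility each pair
#' `(u_l, v_l)` is flipped so that the maximum-magnitude entry of `u_l`
#' is positive (ties broken by the first index).
#'
#' @param x an [omics_matrix()], a `Matrix` sparse matrix, or a dense
#'   matrix (features in rows).
#' @param L number of singular triplets to keep; must not exceed either
#'   dimension.
#' @param seed integer seed for the Lanczos path (the Gram path is
#'   deterministic).
#' @param tol convergence tolerance passed to the Lanczos solver.
#' @param maxit iteration cap for the Lanczos solver.
#' @return An object of class `td_svd` with elements `d` (singular
#'   values, descending), `u` (features x L, orthonormal columns), `v`
#'   (cells x L, orthonormal columns), and `omics_kind` when known.
#' @export
truncated_svd <- function(x, L, seed = 1L, tol = 1e-8, maxit = 1000L) {
  kind <- if (inherits(x, "omics_matrix")) x$omics_kind else NA_character_
  v <- if (inherits(x, "omics_matrix")) x$values else x
  n <- nrow(v); m <- ncol(v)
  stopifnot(is.numeric(L), length(L) == 1, L >= 1)
  if (L > min(n, m))
    stop("L = ", L, " exceeds min(dim) = ", min(n, m))
  if (any(!is.finite(if (methods::is(v, "sparseMatrix")) v@x else v)))
    stop("non-finite entries in input matrix")

  if (min(n, m) <= 4096) {
    fit <- svd_via_gram(v, L)
    # truncation boundary check: a (near-)tied singular value just below
    # the cut means the kept subspace is not unique
    if (!is.null(fit$d_next) && fit$d[1] > 0 &&
        (fit$d[L] - fit$d_next) / fit$d[1] < 1e-10)
      warning("singular value ", L, " is nearly tied with singular value ",
              L + 1, "; the rank-L subspace is not unique")
  } else {
    set.seed(seed)
    s <- irlba::irlba(v, nv = L, tol = tol, maxit = maxit)
    fit <- list(d = s$d[seq_len(L)], u = s$u[, seq_len(L), drop = FALSE],
                v = s$v[, seq_len(L), drop = FALSE])
  }
  fit <- fix_signs(fit)
  rownames(fit$u) <- rownames(v)
  rownames(fit$v) <- colnames(v)
  structure(list(d = fit$d, u = fit$u, v = fit$v, omics_kind = kind),
            class = "td_svd")
}

# Exact truncated SVD through the Gram matrix of the smaller dimension.
# For X (n x m) with m <= n: X'X = V D^2 V', then U = X V D^{-1}.
svd_via_gram <- function(v, L) {
  n <- nrow(v); m <- ncol(v)
  if (m <= n) {
    e <- eigen(as.matrix(Matrix::crossprod(v)), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(L)], 0))
    V <- e$vectors[, seq_len(L), drop = FALSE]
    U <- as.matrix(v %*% V)
    U <- complete_left(U, d)
    out <- list(d = d, u = U, v = V)
  } else {
    e <- eigen(as.matrix(Matrix::tcrossprod(v)), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(L)], 0))
    U <- e$vectors[, seq_len(L), drop = FALSE]
    V <- as.matrix(Matrix::crossprod(v, U))
    V <- complete_left(V, d)
    out <- list(d = d, u = U, v = V)
  }
  if (L < length(e$values))
    out$d_next <- sqrt(max(e$values[L + 1], 0))
  out
}

# Scale columns of X %*% V by 1/d; replace columns whose singular value
# underflows (input numerically rank-deficient) by an orthonormal
# completion so the factor keeps orthonormal columns.
complete_left <- function(U, d) {
  ok <- d > max(d[1], .Machine$double.eps) * 1e-12
  U[, ok] <- sweep(U[, ok, drop = FALSE], 2, d[ok], "/")
  if (!all(ok)) {
    q <- qr.Q(qr(cbind(U[, ok, drop = FALSE],
                       diag(nrow(U))[, seq_len(sum(!ok)), drop = FALSE])))
    U[, !ok] <- q[, sum(ok) + seq_len(sum(!ok)), drop = FALSE]
  }
  U
}

# Deterministic sign convention: largest-|u| entry positive per column.
fix_signs <- function(fit) {
  for (l in seq_along(fit$d)) {
    i <- which.max(abs(fit$u[, l]))
    if (fit$u[i, l] < 0) {
      fit$u[, l] <- -fit$u[, l]
      fit$v[, l] <- -fit$v[, l]
    }
  }
  fit
}

#' @export
print.td_svd <- function(x, ...) {
  cat(sprintf("<td_svd%s> %d features x %d cells, L = %d\n",
              if (is.na(x$omics_kind)) "" else paste0(": ", x$omics_kind),
              nrow(x$u), nrow(x$v), length(x$d)))
  cat("singular values:", format(x$d, digits = 4), "\n")
  invisible(x)
}

#' Project a layer onto its reduced feature space
#'
#' Contracts the layer with the left singular vectors: row `l` of the
#' result is `u_l' X`, giving each omics layer the same L-dimensional
#' feature space regardless of its native feature count. For a matrix of
#' rank at most L this equals `d_l * v_l'` exactly.
#'
#' @param svd a `td_svd` computed from `x`.
#' @param x the same layer passed to [truncated_svd()].
#' @return A dense `L x cells` matrix with cell identifiers as colnames.
#' @export
project_features <- function(svd, x) {
  stopifnot(inherits(svd, "td_svd"))
  v <- if (inherits(x, "omics_matrix")) x$values else x
  if (nrow(v) != nrow(svd$u))
    stop("feature dimension mismatch: matrix has ", nrow(v),
         " rows, SVD has ", nrow(svd$u))
  out <- as.matrix(Matrix::crossprod(svd$u, v))
  colnames(out) <- colnames(v)
  rownames(out) <- NULL
  out
}

#' Stack reduced layers into a rank-by-cell-by-layer tensor
#'
#' Restricts all layers to the cells they share (columns are matched by
#' cell identifier, so each layer may list its cells in any order) and
#' stacks the aligned `L x M` projections into an `L x M x K` array.
#' The cell order of the first layer (canonically expression) is kept.
#' Cells absent from any layer are dropped, never imputed.
#'
#' @param projections named list of `L x cells` matrices from
#'   [project_features()], each with cell identifiers as colnames, in
#'   layer order (canonically expression, methylation, accessibility).
#' @return An object of class `td_tensor`: list with `values` (L x M x K
#'   array), `cell_ids`, `layer_order`.
#' @export
stack_tensor <- function(projections) {
  if (length(projections) < 2)
    stop("need at least 2 layers to build a tensor")
  if (is.null(names(projections)) || any(!nzchar(names(projections))))
    stop("projections must be a named list of layers")
  Ls <- vapply(projections, nrow, 0L)
  if (length(unique(Ls)) != 1)
    stop("all layers must share the same reduced rank L; got ",
         paste(Ls, collapse = ", "))
  shared <- Reduce(intersect, lapply(projections, colnames))
  if (!length(shared))
    stop("no cells shared across all layers")
  shared <- colnames(projections[[1]])[colnames(projections[[1]]) %in% shared]
  arr <- array(0, dim = c(unname(Ls[1]), length(shared), length(projections)),
               dimnames = list(NULL, shared, names(projections)))
  for (k in seq_along(projections))
    arr[, , k] <- projections[[k]][, shared, drop = FALSE]
  structure(list(values = arr, cell_ids = shared,
                 layer_order = names(projections)),
            class = "td_tensor")
}

#' @export
print.td_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<td_tensor> L = %d, M = %d cells, K = %d layers (%s)\n",
              d[1], d[2], d[3], paste(x$layer_order, collapse = ", ")))
  invisible(x)
}
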
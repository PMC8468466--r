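#' Higher-order singular value decomposition of the stacked tensor
#'
#' Decomposes the `L x M x K` tensor `T` as
#' `T = G x1 U1 x2 U2 x3 U3`, where each factor matrix `Un` holds the
#' left singular vectors of the mode-n unfolding of `T` and the core
#' `G` is `T` contracted with the factor transposes. With full factors
#' the decomposition is exact; squared core entries measure how much
#' each triple of factor columns contributes.
#'
#' The mode-n unfolding puts mode n on the rows and cycles the remaining
#' modes in ascending order on the columns, the first remaining mode
#' varying fastest. The mode-2 (cell) unfolding is `M x (L*K)` and has
#' rank at most `L*K`, so only `M' = min(M, L*K)` cell-mode columns are
#' computed; columns beyond the unfolding rank would not be unique and
#' are never used downstream. The sign convention of [truncated_svd()]
#' is applied per factor column.
#'
#' @param tensor a `td_tensor` from [stack_tensor()], or a plain 3-way
#'   array.
#' @return An object of class `td_hosvd`: `core` (`L x M' x K` array),
#'   `mode1_factors` (`L x L`, feature-mode), `mode2_factors`
#'   (`M x M'`, cell-mode, cell ids as rownames), `mode3_factors`
#'   (`K x K`, layer-mode), `cell_ids`, `layer_order`.
#' @export
hosvd <- function(tensor) {
  arr <- if (inherits(tensor, "td_tensor")) tensor$values else tensor
  if (length(dim(arr)) != 3) stop("expected a 3-way tensor")
  if (any(!is.finite(arr))) stop("non-finite entries in tensor")
  d <- dim(arr)
  U <- lapply(1:3, function(n) {
    unf <- unfold(arr, n)
    ncomp <- min(nrow(unf), ncol(unf))
    s <- svd(unf, nu = ncomp, nv = 0)
    u <- s$u
    # per-column deterministic sign: largest-|entry| positive
    for (l in seq_len(ncol(u))) {
      i <- which.max(abs(u[, l]))
      if (u[i, l] < 0) u[, l] <- -u[, l]
    }
    u
  })
  core <- ttm(ttm(ttm(arr, t(U[[1]]), 1), t(U[[2]]), 2), t(U[[3]]), 3)
  cells <- if (inherits(tensor, "td_tensor")) tensor$cell_ids else
    dimnames(arr)[[2]]
  if (!is.null(cells)) rownames(U[[2]]) <- cells
  structure(list(core = core,
                 mode1_factors = U[[1]],
                 mode2_factors = U[[2]],
                 mode3_factors = U[[3]],
                 cell_ids = cells,
                 layer_order = if (inherits(tensor, "td_tensor"))
                   tensor$layer_order else dimnames(arr)[[3]]),
            class = "td_hosvd")
}

# Mode-n matricization: mode n on rows, remaining modes in ascending
# order on columns (first remaining mode fastest).
unfold <- function(arr, n) {
  d <- dim(arr)
  perm <- c(n, setdiff(1:3, n))
  matrix(aperm(arr, perm), nrow = d[n])
}

# Mode-n product: contract mode n of arr with matrix m (rows index the
# new mode size, columns match the old).
ttm <- function(arr, m, n) {
  d <- dim(arr)
  perm <- c(n, setdiff(1:3, n))
  unf <- matrix(aperm(arr, perm), nrow = d[n])
  res <- m %*% unf
  d2 <- d; d2[n] <- nrow(m)
  aperm(array(res, dim = d2[perm]), order(perm))
}

#' Reconstruct a tensor from its HOSVD
#'
#' Triple mode product of the core with the factor matrices. With the
#' full core this reproduces the decomposed tensor to numerical
#' precision.
#'
#' @param x a `td_hosvd` from [hosvd()].
#' @return The reconstructed `L x M x K` array.
#' @export
reconstruct <- function(x) {
  stopifnot(inherits(x, "td_hosvd"))
  fac <- list(x$mode1_factors, x$mode2_factors, x$mode3_factors)
  for (n in 1:3)
    if (ncol(fac[[n]]) != dim(x$core)[n])
      stop("core/factor dimension mismatch on mode ", n, ": core has ",
           dim(x$core)[n], ", factor has ", ncol(fac[[n]]), " columns")
  out <- ttm(ttm(ttm(x$core, x$mode1_factors, 1), x$mode2_factors, 2),
             x$mode3_factors, 3)
  dimnames(out) <- list(NULL, x$cell_ids, x$layer_order)
  out
}

#' @export
print.td_hosvd <- function(x, ...) {
  d <- dim(x$core)
  cat(sprintf("<td_hosvd> core %d x %d x %d; cell-mode factors %d x %d\n",
              d[1], d[2], d[3], nrow(x$mode2_factors), ncol(x$mode2_factors)))
  invisible(x)
}
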
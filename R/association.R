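#' Categorical regression of one cell-mode vector on the classification
#'
#' Fits the component values against the cell classes by ordinary least
#' squares (an intercept plus class indicators; equivalently a one-way
#' layout) and tests whether the class model explains more than the
#' intercept alone with the F statistic on (S - 1, M - S) degrees of
#' freedom. A vector with zero variance carries no class information and
#' is assigned p = 1 by convention rather than NaN.
#'
#' @param v numeric vector, one value per cell.
#' @param labels a [class_labels()] object aligned with `v`, or a factor.
#' @return A list with `coefficients` (per-class means), `intercept`
#'   (grand mean), `fstat`, `df`, and `p.value`.
#' @export
categorical_regression_p <- function(v, labels) {
  g <- if (inherits(labels, "class_labels")) labels$label else factor(labels)
  if (length(v) != length(g))
    stop("vector length (", length(v), ") does not match labels (",
         length(g), ")")
  if (any(!is.finite(v))) stop("non-finite values in vector")
  g <- droplevels(g)
  S <- nlevels(g); M <- length(v)
  if (S < 2) stop("need at least 2 classes")
  if (any(table(g) < 2))
    stop("each class needs at least 2 cells")
  if (M <= S) stop("more classes than residual degrees of freedom allow")
  if (max(v) - min(v) == 0) {
    # constant vector: no explained variance, never coincident
    return(list(coefficients = rep(v[1], S), classes = levels(g),
                intercept = v[1], fstat = 0,
                df = c(df1 = S - 1, df2 = M - S), p.value = 1))
  }
  fit <- stats::lm(v ~ g)
  an <- suppressWarnings(stats::anova(fit))
  fstat <- an[1, "F value"]
  p <- an[1, "Pr(>F)"]
  if (!is.finite(fstat)) { # exact within-class fit: 0 residual variance
    fstat <- Inf
    p <- 0
  }
  means <- tapply(stats::fitted(fit), g, function(z) z[1])
  list(coefficients = as.numeric(means), classes = levels(g),
       intercept = mean(v), fstat = fstat,
       df = c(df1 = S - 1, df2 = M - S), p.value = as.numeric(p))
}

#' Benjamini-Hochberg adjustment of a family of p-values
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`), with input validation.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite numbers in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Identify cell-mode vectors coincident with the classification
#'
#' Runs [categorical_regression_p()] on every column, adjusts the whole
#' family of raw p-values by Benjamini-Hochberg, and flags components
#' whose adjusted p falls below `alpha`. The family is the set of
#' vectors given in one call (e.g. the 10 right singular vectors of one
#' layer, or all K*L cell-mode HOSVD columns); families from separate
#' analyses are never pooled.
#'
#' @param vectors numeric matrix, cells in rows, one component per
#'   column (e.g. `td_svd$v` or `td_hosvd$mode2_factors`).
#' @param labels a [class_labels()] object or factor aligned with the
#'   rows; if the matrix has rownames and `labels` is a `class_labels`,
#'   cells are matched by identifier.
#' @param alpha adjusted-p threshold; default 0.01.
#' @return A tibble of class `td_association`: `component`, `fstat`,
#'   `p.value`, `adj.p.value`, `selected`.
#' @export
select_coincident <- function(vectors, labels, alpha = 0.01) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) < 1) stop("need at least one component vector")
  stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1)
  if (inherits(labels, "class_labels") && !is.null(rownames(vectors))) {
    g <- align_labels(labels, rownames(vectors))
  } else {
    g <- if (inherits(labels, "class_labels")) labels$label else factor(labels)
  }
  fits <- lapply(seq_len(ncol(vectors)), function(l)
    categorical_regression_p(vectors[, l], g))
  p <- vapply(fits, `[[`, 0, "p.value")
  adj <- bh_adjust(p)
  out <- tibble::tibble(
    component = seq_len(ncol(vectors)),
    fstat = vapply(fits, `[[`, 0, "fstat"),
    p.value = p,
    adj.p.value = adj,
    selected = adj < alpha)
  attr(out, "alpha") <- alpha
  attr(out, "coefficients") <- lapply(fits, `[[`, "coefficients")
  class(out) <- c("td_association", class(out))
  out
}

#' Rank feature-mode components by core-tensor energy
#'
#' Scores each feature-mode component `l1` by the summed squared core
#' entries over the coincident cell-mode components and all layers:
#' `score(l1) = sum_{l2 in selected} sum_{l3} G(l1, l2, l3)^2`. The
#' top-scoring `l1` is the feature-mode direction most strongly coupled
#' to the class-coincident cell-mode directions.
#'
#' @param x a `td_hosvd` from [hosvd()].
#' @param selected_l2 integer indices of coincident cell-mode components
#'   (e.g. `dplyr::filter(assoc, selected)$component`).
#' @return A tibble with `l1` and `core_energy`, sorted by decreasing
#'   energy (ties broken by smaller `l1`).
#' @export
rank_l1_by_core <- function(x, selected_l2) {
  stopifnot(inherits(x, "td_hosvd"))
  if (!length(selected_l2))
    stop("no coincident cell-mode vectors: cannot rank feature-mode components")
  selected_l2 <- as.integer(selected_l2)
  if (any(selected_l2 < 1 | selected_l2 > dim(x$core)[2]))
    stop("selected_l2 indices out of range 1..", dim(x$core)[2])
  g2 <- x$core[, selected_l2, , drop = FALSE]^2
  score <- apply(g2, 1, sum)
  ord <- order(-score, seq_along(score))
  tibble::tibble(l1 = ord, core_energy = score[ord])
}
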
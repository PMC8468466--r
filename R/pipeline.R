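#' Run the full tensor-decomposition feature-extraction pipeline
#'
#' Wires the stages end to end: per-layer normalization, truncated SVD
#' to a common rank `L`, stacking into an `L x M x K` tensor over the
#' shared cells, HOSVD, categorical regression of every cell-mode
#' singular vector on the classification with BH correction at `alpha`,
#' core-energy ranking of the feature-mode components over the
#' coincident cell-mode components, back-projection of the top-ranked
#' component(s) to the selection layer's native features, chi-squared
#' feature selection, and (optionally) a 2-D UMAP embedding of the
#' cell-mode factors. Each per-layer SVD's right singular vectors are
#' also tested against the classification, mirroring the per-omics
#' baseline the integrated analysis is compared with.
#'
#' @param expression,methylation,accessibility [omics_matrix()] layers;
#'   at least two must be supplied. Missing-value handling is implicit:
#'   zeros are never imputed.
#' @param labels a [class_labels()] covering the cells of every layer.
#' @param L common reduced rank; default 10.
#' @param alpha BH-adjusted p threshold for both the cell-mode vector
#'   family and the feature family; default 0.01.
#' @param normalization `"dataset1"` (L1-normalize the site-level
#'   layers), `"dataset2"` (leave them raw), or a named character
#'   vector of per-layer choices (`"center_scale"`, `"l1"`, `"none"`).
#' @param top_l1 how many top-ranked feature-mode components enter the
#'   chi-squared statistic; default 1.
#' @param select_layer which layer's native features to select;
#'   default `"expression"`. `NULL`, or a layer that was not supplied,
#'   skips feature selection.
#' @param sigma_center logical; `TRUE` (default) estimates each
#'   component's scale as the sample standard deviation of its
#'   back-projected loadings, `FALSE` uses the zero-mean form.
#' @param embed logical; compute the UMAP embedding (needs more cells
#'   than `n_neighbors`). Default `TRUE`.
#' @param n_neighbors UMAP neighborhood size; default 100.
#' @param seed integer seed for the SVD solver and UMAP.
#' @return An object of class `td_fe`; see [tidy.td_fe()] and
#'   [glance.td_fe()] for tabular views. Main elements: `svd` and
#'   `association_svd` (per layer), `tensor`, `hosvd`, `association`
#'   (cell-mode HOSVD family), `ranking`, `genes`, `embedding`,
#'   `summary`.
#' @export
run_pipeline <- function(expression = NULL, methylation = NULL,
                         accessibility = NULL, labels,
                         L = 10L, alpha = 0.01,
                         normalization = "dataset1",
                         top_l1 = 1L, select_layer = "expression",
                         sigma_center = TRUE,
                         embed = TRUE, n_neighbors = 100L, seed = 1L) {
  layers <- Filter(Negate(is.null),
                   list(expression = expression, methylation = methylation,
                        accessibility = accessibility))
  if (length(layers) < 2)
    stop("need at least 2 omics layers to integrate")
  stopifnot(alpha > 0, alpha < 1)
  plan <- if (length(normalization) == 1 &&
              normalization %in% c("dataset1", "dataset2"))
    normalization_plan(normalization) else normalization
  svds <- list(); projections <- list(); assoc_svd <- list()
  for (nm in names(layers)) {
    x <- layers[[nm]]
    if (L > min(dim(x)))
      stop("L = ", L, " exceeds the dimensions of the ", nm, " layer")
    norm <- apply_normalization(x, plan[[nm]])
    s <- truncated_svd(norm, L = L, seed = seed)
    svds[[nm]] <- s
    projections[[nm]] <- project_features(s, norm)
    assoc_svd[[nm]] <- select_coincident(s$v, labels, alpha = alpha)
  }
  tensor <- stack_tensor(projections)
  hres <- hosvd(tensor)
  assoc <- select_coincident(hres$mode2_factors, labels, alpha = alpha)
  selected_l2 <- assoc$component[assoc$selected]

  ranking <- NULL; genes <- NULL
  if (length(selected_l2)) {
    ranking <- rank_l1_by_core(hres, selected_l2)
    if (!is.null(select_layer) && select_layer %in% names(layers)) {
      l1s <- ranking$l1[seq_len(min(top_l1, nrow(ranking)))]
      loadings <- backproject(hres$mode1_factors, svds[[select_layer]]$u, l1s)
      loadings <- as.matrix(loadings)
      rownames(loadings) <- rownames(svds[[select_layer]]$u)
      chi <- chi2_pvalues(loadings, scales = "estimate",
                          center = sigma_center)
      genes <- select_features(chi$p.value, alpha = alpha,
                               feature_ids = rownames(loadings),
                               statistic = chi$statistic,
                               loadings = loadings)
    } else if (!is.null(select_layer)) {
      message("layer '", select_layer, "' not supplied; feature selection skipped")
    }
  } else {
    message("no cell-mode vector coincident with the classification at alpha = ",
            alpha, "; feature selection skipped")
  }

  embedding <- NULL
  if (embed) {
    if (nrow(hres$mode2_factors) > n_neighbors) {
      embedding <- embed_cells(hres$mode2_factors,
                               n_neighbors = n_neighbors, seed = seed)
    } else {
      message("fewer cells than n_neighbors; embedding skipped")
    }
  }

  summary <- tibble::tibble(
    layer = c(names(layers), "hosvd"),
    family_size = c(rep(L, length(layers)), nrow(assoc)),
    n_coincident = c(unname(vapply(assoc_svd, function(a) sum(a$selected), 0L)),
                     sum(assoc$selected)))
  structure(list(layers = names(layers), svd = svds,
                 association_svd = assoc_svd,
                 tensor = tensor, hosvd = hres, association = assoc,
                 ranking = ranking, genes = genes, embedding = embedding,
                 labels = labels, summary = summary,
                 params = list(L = L, alpha = alpha, plan = plan,
                               top_l1 = top_l1, select_layer = select_layer,
                               sigma_center = sigma_center,
                               n_neighbors = n_neighbors, seed = seed)),
            class = "td_fe")
}

#' @export
print.td_fe <- function(x, ...) {
  cat("<td_fe> integration of", length(x$layers), "layers (",
      paste(x$layers, collapse = ", "), ") over",
      length(x$hosvd$cell_ids), "shared cells\n")
  cat("coincident cell-mode vectors:", sum(x$association$selected), "of",
      nrow(x$association), "at alpha =", x$params$alpha, "\n")
  if (!is.null(x$genes))
    cat("selected features:", sum(x$genes$selected), "of", nrow(x$genes), "\n")
  invisible(x)
}

#' Per-feature results of a pipeline run
#'
#' @param x a `td_fe` object from [run_pipeline()].
#' @param ... ignored.
#' @return The feature-selection tibble (`feature_id`, loadings,
#'   statistic, `p.value`, `adj.p.value`, `selected`), or an empty
#'   tibble when no cell-mode vector was coincident.
#' @method tidy td_fe
#' @export
tidy.td_fe <- function(x, ...) {
  if (is.null(x$genes)) return(tibble::tibble())
  tibble::as_tibble(x$genes)
}

#' One-row summary of a pipeline run
#'
#' @param x a `td_fe` object from [run_pipeline()].
#' @param ... ignored.
#' @return A one-row tibble: cells, layers, rank, coincident cell-mode
#'   vector count, selected feature count, alpha.
#' @method glance td_fe
#' @export
glance.td_fe <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$hosvd$cell_ids),
    n_layers = length(x$layers),
    L = x$params$L,
    n_cell_vectors = nrow(x$association),
    n_coincident = sum(x$association$selected),
    n_selected_features = if (is.null(x$genes)) 0L else sum(x$genes$selected),
    alpha = x$params$alpha)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
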
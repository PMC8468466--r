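#' Sparse feature-by-cell matrix for one omics layer
#'
#' An `omics_matrix` wraps a [Matrix::sparseMatrix()] (class `dgCMatrix`)
#' whose rows are features and whose columns are cells, together with the
#' kind of omics layer it holds. Missing observations are implicit zeros:
#' they are never stored and never imputed. For a methylation layer every
#' stored entry is +1 (methylated call) or -1 (unmethylated call); for an
#' accessibility layer every stored entry is a nonnegative binned total;
#' for an expression layer entries are nonnegative counts.
#'
#' @param values a matrix coercible to `dgCMatrix`, features in rows.
#' @param feature_ids character vector of unique feature identifiers
#'   (gene symbols, `"chrom:pos"` site keys, or `"chrom:start-end"` bin
#'   keys), one per row.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column.
#' @param omics_kind one of `"expression"`, `"methylation"`,
#'   `"accessibility"`.
#'
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, feature_ids, cell_ids,
                         omics_kind = c("expression", "methylation",
                                        "accessibility")) {
  omics_kind <- match.arg(omics_kind)
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(feature_ids))
    stop("number of rows (", nrow(values), ") does not match number of ",
         "feature_ids (", length(feature_ids), ")")
  if (ncol(values) != length(cell_ids))
    stop("number of columns (", ncol(values), ") does not match number of ",
         "cell_ids (", length(cell_ids), ")")
  dup_f <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup_f))
    stop("duplicated feature_ids: ", paste(utils::head(dup_f, 5), collapse = ", "))
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c))
    stop("duplicated cell_ids: ", paste(utils::head(dup_c, 5), collapse = ", "))
  values <- Matrix::drop0(values)
  if (omics_kind == "methylation" && !all(values@x %in% c(-1, 1)))
    stop("methylation entries must be ternary: stored values in {-1, +1}")
  if (omics_kind == "accessibility" && any(values@x < 0))
    stop("accessibility entries must be nonnegative")
  dimnames(values) <- list(feature_ids, cell_ids)
  structure(list(values = values, omics_kind = omics_kind),
            class = "omics_matrix")
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature identifiers of an omics matrix
#' @param x an `omics_matrix`.
#' @return Character vector of row identifiers.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Cell identifiers of an omics matrix
#' @param x an `omics_matrix`.
#' @return Character vector of column identifiers.
#' @export
cell_ids <- function(x) colnames(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  nz <- Matrix::nnzero(x$values)
  cat(sprintf("<omics_matrix: %s> %d features x %d cells, %d stored (%.3f nonzero)\n",
              x$omics_kind, nrow(x$values), ncol(x$values), nz,
              nz / prod(dim(x$values))))
  invisible(x)
}

#' Fraction of explicitly stored (nonzero) entries
#' @param x an `omics_matrix`.
#' @return A number in \[0, 1\].
#' @export
nonzero_fraction <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  Matrix::nnzero(x$values) / prod(dim(x$values))
}

#' Cell classification labels
#'
#' Pairs every cell with exactly one class label. The categorical
#' regression downstream needs at least two classes and at least two
#' cells per class to have an F distribution with positive degrees of
#' freedom.
#'
#' @param cell_ids character vector of unique cell identifiers.
#' @param label vector of class labels, one per cell (coerced to factor).
#' @return An object of class `class_labels`: a data frame with columns
#'   `cell_id` and `label`.
#' @export
class_labels <- function(cell_ids, label) {
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids))
    stop("duplicated cell_ids in labels: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (length(label) != length(cell_ids))
    stop("length of label (", length(label), ") does not match cell_ids (",
         length(cell_ids), ")")
  label <- factor(label)
  if (nlevels(label) < 2)
    stop("need at least 2 classes, got ", nlevels(label))
  small <- names(which(table(label) < 2))
  if (length(small))
    stop("each class needs at least 2 cells; too small: ",
         paste(small, collapse = ", "))
  out <- tibble::tibble(cell_id = cell_ids, label = label)
  class(out) <- c("class_labels", class(out))
  out
}

#' Read cell classification labels from a TSV file
#'
#' Expects two tab-separated columns, `cell_id` and `class`, with a
#' header row. Gzip-compressed files are read transparently.
#'
#' @param path path to the labels file.
#' @return A [class_labels()] object.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character"),
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("labels file must have two columns: cell_id, class")
  class_labels(df[[1]], df[[2]])
}

# Align a class_labels object to a given cell order; error on missing cells.
align_labels <- function(labels, cells) {
  idx <- match(cells, labels$cell_id)
  if (anyNA(idx))
    stop("no class label for cell(s): ",
         paste(utils::head(cells[is.na(idx)], 5), collapse = ", "))
  droplevels(labels$label[idx])
}
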
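#' Read a genes-by-cells expression count matrix from TSV
#'
#' The file must have a header row of cell identifiers and a first column
#' of gene identifiers; remaining entries are nonnegative numeric counts.
#' Gzip compression is handled transparently. Row and column order are
#' preserved as-is; zeros become implicit in the sparse storage.
#'
#' @param path path to the TSV file.
#' @return An [omics_matrix()] with `omics_kind = "expression"`.
#' @export
read_expression_matrix <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                      check.names = FALSE, quote = "", comment.char = ""),
    error = function(e) stop("no rows in expression file: ", path))
  if (nrow(df) == 0) stop("no rows in expression file: ", path)
  genes <- as.character(df[[1]])
  mat <- df[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    col <- mat[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("non-numeric value at row ", bad, ", column '", names(mat)[j],
           "' of ", path)
    }
  }
  m <- as.matrix(mat)
  if (any(m < 0)) stop("negative counts in expression file: ", path)
  omics_matrix(m, feature_ids = genes, cell_ids = colnames(mat),
               omics_kind = "expression")
}

#' Read per-cell genomic site observations
#'
#' Each file holds one cell's observations as three tab-separated columns
#' `chrom`, `pos`, `value` (header optional, auto-detected; gzip
#' transparent). Input positions are 1-based and are converted to the
#' package's internal 0-based convention on read.
#'
#' @param paths character vector of file paths, one per cell.
#' @param cells character vector of cell identifiers, parallel to
#'   `paths`; defaults to the file base names stripped of extensions.
#' @return A named list of data frames with columns `chrom` (character),
#'   `pos` (0-based integer) and `value` (numeric), suitable for
#'   [build_ternary_methylation()] and [bin_accessibility()].
#' @export
read_site_files <- function(paths, cells = NULL) {
  if (is.null(cells))
    cells <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(paths))
  if (anyDuplicated(cells))
    stop("duplicated cell identifiers among site files")
  out <- lapply(paths, function(p) {
    first <- utils::read.table(p, sep = "\t", nrows = 1,
                               colClasses = "character")
    header <- is.na(suppressWarnings(as.numeric(first[[2]])))
    df <- utils::read.table(p, sep = "\t", header = header,
                            colClasses = c("character", "numeric", "numeric"),
                            quote = "", comment.char = "")
    names(df) <- c("chrom", "pos", "value")
    df$pos <- as.integer(df$pos) - 1L
    df
  })
  names(out) <- cells
  out
}

# Validate a per-cell site list and return a combined data frame with a
# `cell` column. `check` validates the value range per layer.
combine_sites <- function(per_cell_sites, check) {
  if (!length(per_cell_sites) ||
      !any(vapply(per_cell_sites, nrow, 0L) > 0))
    stop("no site observations in any cell")
  if (is.null(names(per_cell_sites)) || anyDuplicated(names(per_cell_sites)))
    stop("per_cell_sites must be a named list with unique cell identifiers")
  pieces <- lapply(names(per_cell_sites), function(cell) {
    df <- per_cell_sites[[cell]]
    if (!nrow(df)) return(NULL)
    stopifnot(all(c("chrom", "pos", "value") %in% names(df)))
    if (any(df$pos < 0)) stop("negative position in cell ", cell)
    if (any(!nzchar(df$chrom))) stop("empty chromosome name in cell ", cell)
    check(df, cell)
    data.frame(cell = cell, chrom = as.character(df$chrom),
               pos = as.integer(df$pos), value = as.numeric(df$value))
  })
  do.call(rbind, pieces)
}

# Order site keys by (chrom lexicographic, position numeric) and return
# the ordered unique key strings.
order_site_keys <- function(chrom, pos) {
  u <- !duplicated(paste0(chrom, ":", pos))
  chrom <- chrom[u]; pos <- pos[u]
  o <- order(chrom, pos)
  list(key = paste0(chrom, ":", pos)[o], chrom = chrom[o], pos = pos[o])
}

#' Build a ternary methylation matrix from per-cell site observations
#'
#' The feature set is the union of sites observed in at least one cell,
#' sorted by chromosome then position. For each observed (site, cell)
#' pair the stored entry is +1 when the methylation level is at or above
#' `call_threshold` and -1 otherwise; unobserved pairs stay implicit
#' zeros, so missingness is encoded as a neutral value instead of being
#' imputed.
#'
#' @param per_cell_sites named list (cell id -> data frame with columns
#'   `chrom`, `pos` (0-based), `value` in \[0, 1\]), e.g. from
#'   [read_site_files()].
#' @param call_threshold methylation level at or above which a site is
#'   called methylated. Default 0.5.
#' @return An [omics_matrix()] with `omics_kind = "methylation"` and
#'   feature ids `"chrom:pos"`.
#' @export
build_ternary_methylation <- function(per_cell_sites, call_threshold = 0.5) {
  stopifnot(is.numeric(call_threshold), call_threshold > 0, call_threshold < 1)
  sites <- combine_sites(per_cell_sites, check = function(df, cell) {
    bad <- which(df$value < 0 | df$value > 1)
    if (length(bad))
      stop("methylation level outside [0, 1] in cell ", cell,
           " at ", df$chrom[bad[1]], ":", df$pos[bad[1]])
  })
  key <- paste0(sites$chrom, ":", sites$pos)
  dup <- duplicated(paste0(sites$cell, "\r", key))
  if (any(dup)) {
    d <- which(dup)[1]
    stop("duplicated site within one cell: (", sites$cell[d], ", ", key[d], ")")
  }
  feat <- order_site_keys(sites$chrom, sites$pos)
  cells <- names(per_cell_sites)
  values <- Matrix::sparseMatrix(
    i = match(key, feat$key),
    j = match(sites$cell, cells),
    x = ifelse(sites$value >= call_threshold, 1, -1),
    dims = c(length(feat$key), length(cells)))
  empty <- setdiff(cells, sites$cell)
  if (length(empty))
    warning("cell(s) with zero observations retained as all-zero columns: ",
            paste(utils::head(empty, 5), collapse = ", "))
  omics_matrix(values, feature_ids = feat$key, cell_ids = cells,
               omics_kind = "methylation")
}

#' Sum accessibility signal into fixed-width genomic bins
#'
#' Divides each chromosome into consecutive half-open windows
#' `[m*bin_size, (m+1)*bin_size)` and sums the site values falling in
#' each window per cell. The default 200-nt width approximates one
#' nucleosome (about 147 nt of wrapped DNA plus linker). Only bins with
#' at least one observation in at least one cell become features, sorted
#' by chromosome then start.
#'
#' @param per_cell_sites named list (cell id -> data frame with columns
#'   `chrom`, `pos` (0-based), `value` >= 0), e.g. from
#'   [read_site_files()].
#' @param bin_size bin width in nucleotides; default 200.
#' @return An [omics_matrix()] with `omics_kind = "accessibility"` and
#'   feature ids `"chrom:start-end"` (0-based, half-open).
#' @export
bin_accessibility <- function(per_cell_sites, bin_size = 200L) {
  stopifnot(is.numeric(bin_size), bin_size >= 1)
  bin_size <- as.integer(bin_size)
  sites <- combine_sites(per_cell_sites, check = function(df, cell) {
    bad <- which(df$value < 0)
    if (length(bad))
      stop("negative accessibility value in cell ", cell,
           " at ", df$chrom[bad[1]], ":", df$pos[bad[1]])
  })
  start <- (sites$pos %/% bin_size) * bin_size
  bins <- order_site_keys(sites$chrom, start)
  key <- paste0(sites$chrom, ":", start)
  cells <- names(per_cell_sites)
  values <- Matrix::sparseMatrix(
    i = match(key, bins$key),
    j = match(sites$cell, cells),
    x = sites$value,
    dims = c(length(bins$key), length(cells)))  # duplicate (i,j) pairs sum
  empty <- setdiff(cells, sites$cell)
  if (length(empty))
    warning("cell(s) with zero observations retained as all-zero columns: ",
            paste(utils::head(empty, 5), collapse = ", "))
  ids <- paste0(bins$chrom, ":", bins$pos, "-", bins$pos + bin_size)
  omics_matrix(values, feature_ids = ids, cell_ids = cells,
               omics_kind = "accessibility")
}

#' Save / load an omics matrix as MatrixMarket plus TSV sidecars
#'
#' `save_sparse()` writes `<path>.mtx` (coordinate format), sidecars
#' `<path>.features.tsv` and `<path>.cells.tsv` (one identifier per
#' line), and `<path>.kind.txt`. `load_sparse()` reverses it exactly:
#' values, identifiers, ordering and `omics_kind` round-trip losslessly.
#'
#' @param x an [omics_matrix()].
#' @param path path prefix (no extension).
#' @return `save_sparse()` returns `path` invisibly; `load_sparse()`
#'   returns the reconstructed [omics_matrix()].
#' @export
save_sparse <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  dimnames(v) <- NULL
  Matrix::writeMM(v, paste0(path, ".mtx"))
  writeLines(feature_ids(x), paste0(path, ".features.tsv"))
  writeLines(cell_ids(x), paste0(path, ".cells.tsv"))
  writeLines(x$omics_kind, paste0(path, ".kind.txt"))
  invisible(path)
}

#' @rdname save_sparse
#' @export
load_sparse <- function(path) {
  for (ext in c(".mtx", ".features.tsv", ".cells.tsv", ".kind.txt"))
    if (!file.exists(paste0(path, ext)))
      stop("missing file for sparse bundle: ", paste0(path, ext))
  v <- Matrix::readMM(paste0(path, ".mtx"))
  feats <- readLines(paste0(path, ".features.tsv"))
  cells <- readLines(paste0(path, ".cells.tsv"))
  kind <- readLines(paste0(path, ".kind.txt"))[1]
  omics_matrix(v, feature_ids = feats, cell_ids = cells, omics_kind = kind)
}
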
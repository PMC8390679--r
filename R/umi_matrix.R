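#' UMI count matrix container
#'
#' A light container for droplet scRNA-seq data: a sparse nonnegative integer
#' genes x cells matrix plus a per-cell metadata table. Gene ids and barcodes
#' are carried as dimnames and must be unique.
#'
#' @param counts A genes x cells matrix (dense or any `Matrix` sparse class)
#'   of nonnegative integers with unique rownames (gene ids) and colnames
#'   (barcodes).
#' @param cell_meta Optional data.frame of per-cell metadata (e.g. condition,
#'   day, batch), with one row per barcode. Row names (or a `barcode` column)
#'   must match the matrix barcodes.
#' @return An object of class `umi_matrix` with elements `counts`
#'   (a `dgCMatrix`) and `cell_meta` (a data.frame keyed by barcode).
#' @export
umi_matrix <- function(counts, cell_meta = NULL) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts))) {
    if (nrow(counts) == 0) rownames(counts) <- character(0)
    else stop("counts must have gene ids as rownames")
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) == 0) colnames(counts) <- character(0)
    else stop("counts must have barcodes as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate barcodes")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v)))) {
    stop("counts must be nonnegative integers")
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = colnames(counts))
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if ("barcode" %in% names(cell_meta) &&
        !identical(rownames(cell_meta), colnames(counts))) {
      rownames(cell_meta) <- cell_meta$barcode
      cell_meta$barcode <- NULL
    }
    if (!setequal(rownames(cell_meta), colnames(counts))) {
      stop("cell_meta barcodes do not match count matrix barcodes")
    }
    cell_meta <- cell_meta[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "umi_matrix")
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

#' @rdname umi_matrix
#' @param x,m A `umi_matrix`.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname umi_matrix
#' @export
barcodes <- function(x) colnames(x$counts)

#' @rdname umi_matrix
#' @export
n_genes <- function(x) nrow(x$counts)

#' @rdname umi_matrix
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname umi_matrix
#' @export
cell_totals <- function(x) Matrix::colSums(x$counts)

#' @rdname umi_matrix
#' @param genes,cells Character, logical or integer index of genes / cells to
#'   retain (default: all).
#' @export
umi_subset <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "umi_matrix"))
  counts <- m$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  umi_matrix(counts, m$cell_meta[colnames(counts), , drop = FALSE])
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf(
    "umi_matrix: %d genes x %d cells (%.2f%% nonzero)\n",
    nrow(x$counts), ncol(x$counts),
    if (prod(dim(x$counts)) > 0) {
      100 * length(x$counts@x) / prod(dim(x$counts))
    } else 0
  ))
  if (ncol(x$cell_meta)) {
    cat("cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  }
  invisible(x)
}
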
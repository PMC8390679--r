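#' Read a 10x-style matrix triplet
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` (plain or gzipped,
#' Matrix Market 1-based coordinate format, genes as rows) from a directory.
#' If a `metadata.csv` with a `barcode` column is present it is attached as
#' per-cell metadata.
#'
#' @param dir Directory containing the triplet.
#' @return A [umi_matrix].
#' @export
read_tenx_triplet <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  find1 <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("missing file: ", base, " in ", dir)
  }
  mtx <- find1("matrix.mtx")
  m <- Matrix::readMM(mtx)
  read_ids <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    on.exit(close(con))
    lines <- readLines(con)
    sub("\t.*$", "", lines)
  }
  feats <- read_ids(find1("features.tsv"))
  bcs <- read_ids(find1("barcodes.tsv"))
  if (length(feats) != nrow(m)) {
    stop(sprintf("features.tsv has %d rows but matrix has %d rows",
                 length(feats), nrow(m)))
  }
  if (length(bcs) != ncol(m)) {
    stop(sprintf("barcodes.tsv has %d rows but matrix has %d columns",
                 length(bcs), ncol(m)))
  }
  vals <- if (is(m, "nMatrix")) rep(1, Matrix::nnzero(m)) else m@x
  if (length(vals) && (any(vals < 0) || any(vals != floor(vals)))) {
    stop("matrix.mtx contains negative or non-integer entries")
  }
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(feats, bcs)
  meta <- NULL
  meta_file <- file.path(dir, "metadata.csv")
  if (file.exists(meta_file)) {
    meta <- read.csv(meta_file, stringsAsFactors = FALSE)
    if (!"barcode" %in% names(meta)) {
      stop("metadata.csv must have a 'barcode' column")
    }
    rownames(meta) <- meta$barcode
    meta$barcode <- NULL
    meta <- meta[bcs, , drop = FALSE]
  }
  umi_matrix(m, meta)
}

#' Write a 10x-style matrix triplet
#'
#' Writes `matrix.mtx` (Matrix Market integer coordinate, 1-based, canonical
#' column-major entry order so write-read-write round trips are
#' byte-identical), `features.tsv` (id, name, type) and `barcodes.tsv`. If
#' the object carries per-cell metadata, a `metadata.csv` is written too.
#'
#' @param m A [umi_matrix].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tenx_triplet <- function(m, dir) {
  stopifnot(inherits(m, "umi_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- m$counts
  # dgCMatrix slots are already in canonical column-major, row-sorted order
  i <- x@i + 1L
  j <- rep(seq_len(ncol(x)), diff(x@p))
  v <- x@x
  keep <- v != 0
  header <- c(
    "%%MatrixMarket matrix coordinate integer general",
    "%",
    paste(nrow(x), ncol(x), sum(keep))
  )
  body <- if (any(keep)) {
    paste(i[keep], j[keep], format(v[keep], scientific = FALSE, trim = TRUE))
  } else {
    character(0)
  }
  writeLines(c(header, body), file.path(dir, "matrix.mtx"))
  gids <- rownames(x) %||% character(0)
  writeLines(if (length(gids)) paste(gids, gids, "Gene Expression", sep = "\t")
             else character(0), file.path(dir, "features.tsv"))
  writeLines(colnames(x) %||% character(0), file.path(dir, "barcodes.tsv"))
  if (ncol(m$cell_meta)) {
    write.csv(cbind(barcode = rownames(m$cell_meta), m$cell_meta),
              file.path(dir, "metadata.csv"), row.names = FALSE)
  }
  invisible(dir)
}
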
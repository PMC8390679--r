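#' QC thresholds
#'
#' Defaults follow the standard droplet QC used for the embryo atlas:
#' cells with a mitochondrial UMI fraction of 7.5% or more (strict `<` is
#' retained) or with fewer than `min_genes_per_cell` expressed genes are
#' dropped; genes expressed in fewer than three of the remaining cells are
#' then dropped.
#'
#' @param max_mito_fraction Cells with mito fraction `>=` this are dropped
#'   (default 0.075).
#' @param min_cells_per_gene Genes must be expressed (count > 0) in at least
#'   this many retained cells (default 3).
#' @param min_genes_per_cell Cells must express at least this many genes
#'   (default 500).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.075,
                          min_cells_per_gene = 3,
                          min_genes_per_cell = 500) {
  assert_fraction(max_mito_fraction, "max_mito_fraction",
                  lo = 0, hi = 1, lo_open = TRUE)
  assert_count(min_cells_per_gene, "min_cells_per_gene")
  assert_count(min_genes_per_cell, "min_genes_per_cell")
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_genes_per_cell = as.integer(min_genes_per_cell)),
            class = "qc_thresholds")
}

#' Apply QC filters
#'
#' Filtering order is deterministic: cells first (mito fraction and
#' expressed-gene count), then genes (expression in at least
#' `min_cells_per_gene` of the *retained* cells). Applying the filter to its
#' own output changes nothing.
#'
#' @param m A [umi_matrix].
#' @param thr A [qc_thresholds].
#' @param mito_genes Character vector of mitochondrial gene ids (must be a
#'   subset of the matrix gene ids).
#' @return List with `umi` (filtered matrix) and `qc_table`, a per-input-cell
#'   data.frame of mito fraction, total UMI, expressed genes, a `kept` flag
#'   and a drop `reason`.
#' @export
apply_qc_filters <- function(m, thr = qc_thresholds(), mito_genes) {
  stopifnot(inherits(m, "umi_matrix"), inherits(thr, "qc_thresholds"))
  missing <- setdiff(mito_genes, gene_ids(m))
  if (length(missing)) {
    stop("mito_genes absent from matrix: ", paste(head(missing), collapse = ", "))
  }
  x <- m$counts
  n_umi <- Matrix::colSums(x)
  mito <- if (length(mito_genes)) {
    Matrix::colSums(x[mito_genes, , drop = FALSE]) / pmax(n_umi, 1)
  } else {
    rep(0, ncol(x))
  }
  genes_per_cell <- Matrix::colSums(x > 0)
  drop_mito <- mito >= thr$max_mito_fraction
  drop_genes <- genes_per_cell < thr$min_genes_per_cell
  kept <- !(drop_mito | drop_genes)
  reason <- rep("", ncol(x))
  reason[drop_genes] <- "low_gene_count"
  reason[drop_mito] <- ifelse(nzchar(reason[drop_mito]),
                              "high_mito;low_gene_count", "high_mito")
  qc_table <- data.frame(
    barcode = colnames(x), n_umi = as.numeric(n_umi),
    n_genes = as.integer(genes_per_cell), mito_fraction = as.numeric(mito),
    kept = kept, reason = reason, stringsAsFactors = FALSE
  )
  xk <- x[, kept, drop = FALSE]
  gene_cells <- Matrix::rowSums(xk > 0)
  keep_genes <- gene_cells >= thr$min_cells_per_gene
  xk <- xk[keep_genes, , drop = FALSE]
  if (ncol(xk) == 0 || nrow(xk) == 0) {
    warning("QC filtering removed all cells or all genes")
  }
  list(
    umi = umi_matrix(xk, m$cell_meta[colnames(xk), , drop = FALSE]),
    qc_table = qc_table
  )
}

#' Estimate the ambient contamination fraction from exclusive reporters
#'
#' The ambient profile `b` is the aggregate count profile over all
#' cell-containing barcodes normalized to a simplex. The contamination
#' fraction is the Poisson maximum-likelihood ratio of observed reporter
#' counts in a population that cannot express them (e.g. CG genes in
#' POU5F1-positive epiblast cells) to the counts expected if those cells were
#' fully ambient:
#' \deqn{\hat\rho = \frac{\sum_{c \in pop}\sum_{g \in rep} x_{gc}}
#'   {\sum_{c \in pop} N_c \sum_{g \in rep} b_g}}
#' clamped to \[0, 1\].
#'
#' @param m A [umi_matrix].
#' @param reporter_genes Gene ids endogenously exclusive to a producer
#'   population (absent from the reporter population).
#' @param reporter_population Barcodes of the non-expressing population.
#' @return An `ambient_estimate` list: `rho`, `ambient_profile` (named,
#'   sums to 1), `reporter_genes`, `reporter_population`,
#'   `producer_population` (barcodes outside the reporter population whose
#'   reporter share exceeds 1%).
#' @export
estimate_ambient_fraction <- function(m, reporter_genes, reporter_population) {
  stopifnot(inherits(m, "umi_matrix"))
  if (!length(reporter_population)) stop("reporter_population is empty")
  missing <- setdiff(reporter_genes, gene_ids(m))
  if (length(missing)) {
    stop("reporter genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  if (!all(reporter_population %in% barcodes(m))) {
    stop("reporter_population contains unknown barcodes")
  }
  x <- m$counts
  agg <- Matrix::rowSums(x)
  if (sum(agg) == 0) stop("empty matrix")
  b <- as.numeric(agg) / sum(agg)
  names(b) <- rownames(x)
  b_rep <- sum(b[reporter_genes])
  if (b_rep == 0) {
    stop("reporter genes have zero aggregate counts; cannot estimate rho")
  }
  pop <- x[, reporter_population, drop = FALSE]
  observed <- sum(pop[reporter_genes, , drop = FALSE])
  expected_full <- sum(Matrix::colSums(pop)) * b_rep
  rho <- min(1, max(0, observed / expected_full))
  other <- setdiff(colnames(x), reporter_population)
  share <- Matrix::colSums(x[reporter_genes, other, drop = FALSE]) /
    pmax(Matrix::colSums(x[, other, drop = FALSE]), 1)
  structure(list(
    rho = rho, ambient_profile = b, reporter_genes = reporter_genes,
    reporter_population = reporter_population,
    producer_population = other[share > 0.01]
  ), class = "ambient_estimate")
}

#' Remove estimated ambient counts from a matrix
#'
#' Deterministic per-entry subtraction: each entry becomes
#' `max(0, round(x_gc - rho * N_c * b_g))`, so corrected totals never exceed
#' the originals and the matrix stays integral and nonnegative. Entries that
#' are already zero stay zero.
#'
#' @param m A [umi_matrix].
#' @param est An `ambient_estimate` from [estimate_ambient_fraction()].
#' @return The corrected [umi_matrix].
#' @export
correct_ambient <- function(m, est) {
  stopifnot(inherits(m, "umi_matrix"), inherits(est, "ambient_estimate"))
  if (est$rho == 0) return(m)
  x <- m$counts
  b <- est$ambient_profile[rownames(x)]
  if (anyNA(b)) stop("ambient profile does not cover all genes in the matrix")
  N <- Matrix::colSums(x)
  i <- x@i + 1L
  j <- rep(seq_len(ncol(x)), diff(x@p))
  expected <- est$rho * N[j] * b[i]
  newx <- pmax(0, round(x@x - expected))
  out <- x
  out@x <- as.numeric(newx)
  out <- Matrix::drop0(out)
  umi_matrix(out, m$cell_meta)
}
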
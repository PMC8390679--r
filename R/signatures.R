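#' Score a gene signature in every cell
#'
#' The score is the signature's share of the cell's transcripts, scaled to
#' percent: `s_c = 100 * sum(x_gc, g in signature) / N_c`. Computed on raw
#' (post-QC, pre-residual) UMI counts; signature genes absent from the matrix
#' contribute zero and are flagged via `attr(, "missing_genes")`.
#'
#' @param m A [umi_matrix] with positive cell totals.
#' @param sig Character vector of gene ids (duplicates not allowed), or a
#'   single-element named list.
#' @return Named numeric vector of per-barcode scores in `[0, 100]`.
#' @export
score_signature <- function(m, sig) {
  stopifnot(inherits(m, "umi_matrix"))
  if (is.list(sig)) sig <- sig[[1]]
  if (anyDuplicated(sig)) stop("signature contains duplicate genes")
  if (!length(sig)) stop("empty signature")
  N <- cell_totals(m)
  if (any(N == 0)) stop("cells with zero total counts")
  present <- intersect(sig, gene_ids(m))
  s <- if (length(present)) {
    100 * Matrix::colSums(m$counts[present, , drop = FALSE]) / N
  } else {
    warning("no signature genes present in the matrix; scores are all zero")
    setNames(rep(0, n_cells(m)), barcodes(m))
  }
  attr(s, "missing_genes") <- setdiff(sig, present)
  s
}

#' Score several signatures at once
#'
#' @param m A [umi_matrix].
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @return A signatures x cells matrix of scores.
#' @export
score_signatures <- function(m, sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- t(vapply(sets, function(s) {
    as.numeric(suppressWarnings(score_signature(m, s)))
  }, numeric(n_cells(m))))
  dimnames(out) <- list(names(sets), barcodes(m))
  out
}
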
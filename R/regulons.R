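#' Expression prefilter for regulon scoring
#'
#' Keeps genes with at least `min_umi_per_frac` UMI counts in 1% of the cells
#' in total, present in at least 1% of the cells: with `f = cell_frac`,
#' `min_cells = ceiling(f * n_cells)` and
#' `min_counts = min_umi_per_frac * min_cells`; a gene passes if its total
#' count is `>= min_counts` AND it is expressed (count > 0) in
#' `>= min_cells` cells. At 1300 cells this gives the canonical
#' (39 counts, 13 cells) thresholds.
#'
#' @param m A [umi_matrix].
#' @param min_umi_per_frac UMI per "1% of cells" unit (default 3).
#' @param cell_frac Cell fraction (default 0.01).
#' @return Character vector of retained gene ids; the thresholds are in
#'   `attr(, "thresholds")`.
#' @export
prefilter_genes <- function(m, min_umi_per_frac = 3, cell_frac = 0.01) {
  stopifnot(inherits(m, "umi_matrix"), n_cells(m) >= 1)
  min_cells <- as.integer(ceiling(cell_frac * n_cells(m)))
  min_counts <- as.integer(min_umi_per_frac * min_cells)
  tot <- Matrix::rowSums(m$counts)
  ncell <- Matrix::rowSums(m$counts > 0)
  keep <- tot >= min_counts & ncell >= min_cells
  out <- gene_ids(m)[keep]
  attr(out, "thresholds") <- c(min_counts = min_counts, min_cells = min_cells)
  out
}

#' Recovery-curve AUC regulon activity scores
#'
#' For each cell, genes are ranked by decreasing count with seeded random
#' tie-breaks (sparse UMI data is tie-dominated, so tie handling is explicit
#' and reproducible). With `hits(x)` = number of regulon genes at rank
#' `<= x`, the activity is the normalized partial area
#' `A = sum_{x=1..k} hits(x) / sum_{x=1..k} min(x, |R|)` where `|R|` is the
#' number of regulon genes present in the matrix.
#'
#' @param m A [umi_matrix] (typically prefiltered, see [prefilter_genes()]).
#' @param regulons Named list TF -> target gene ids (the TF is conventionally
#'   included among its own genes).
#' @param k Rank cutoff (default `ceiling(0.05 * n_genes)`).
#' @param seed Tie-break seed.
#' @return An `auc_matrix`: regulons x cells numeric matrix with attributes
#'   `k` and `missing_genes` (per regulon). Regulons with no present genes
#'   get an all-`NaN` row and a warning.
#' @export
auc_score <- function(m, regulons, k = NULL, seed = 1) {
  stopifnot(inherits(m, "umi_matrix"), is.list(regulons),
            !is.null(names(regulons)))
  ng <- n_genes(m); nc <- n_cells(m)
  if (is.null(k)) k <- as.integer(ceiling(0.05 * ng))
  if (k > ng) stop("rank cutoff k exceeds the number of genes")
  present <- lapply(regulons, function(gs) intersect(gs, gene_ids(m)))
  sizes <- lengths(present)
  if (any(sizes == 0)) {
    warning("regulon(s) with no genes present: ",
            paste(names(regulons)[sizes == 0], collapse = ", "))
  }
  # per-regulon membership indicator over gene indices
  memb <- lapply(present, function(gs) match(gs, gene_ids(m)))
  denom <- vapply(sizes, function(s) sum(pmin(seq_len(k), s)), numeric(1))
  X <- as.matrix(m$counts)
  A <- matrix(NaN, length(regulons), nc,
              dimnames = list(names(regulons), barcodes(m)))
  with_seed(seed, {
    for (cix in seq_len(nc)) {
      tie_key <- runif(ng)
      ord <- order(-X[, cix], tie_key)           # gene index by rank
      rank_of <- integer(ng); rank_of[ord] <- seq_len(ng)
      for (ri in seq_along(memb)) {
        if (sizes[ri] == 0) next
        r <- rank_of[memb[[ri]]]
        r <- r[r <= k]
        A[ri, cix] <- sum(k - r + 1) / denom[ri]
      }
    }
  })
  attr(A, "k") <- k
  attr(A, "missing_genes") <- lapply(seq_along(regulons), function(ri) {
    setdiff(regulons[[ri]], present[[ri]])
  })
  class(A) <- c("auc_matrix", class(A))
  A
}

#' Binarize one regulon's AUC distribution
#'
#' If the dip test does not reject unimodality (`p >= alpha`) the threshold
#' is mean + 2 sd; otherwise the AUC distribution is treated as bimodal and
#' the threshold is the trough of the Gaussian-kernel smoothed density
#' between its two highest local maxima (512-point grid on
#' `[min - 3h, max + 3h]`). Cells are active iff `AUC > tau` (strict; ties
#' at the threshold are inactive). Constant input falls back to
#' `tau = mean` with no active cells.
#'
#' @param auc_values Numeric vector of one regulon's per-cell AUC.
#' @param dip List with `D` and `p` from [dip_test()] (computed internally
#'   when `NULL`).
#' @param alpha Dip-test significance level (default 0.05).
#' @param bandwidth KDE bandwidth (default Silverman's rule).
#' @param n_boot,seed Passed to [dip_test()] when `dip` is `NULL`.
#' @return List with `threshold`, `rule` (`"mean+2sd"`, `"kde-trough"` or
#'   `"degenerate"`), `active` (logical vector), `modality`, `dip`.
#' @export
binarize_regulon <- function(auc_values, dip = NULL, alpha = 0.05,
                             bandwidth = NULL, n_boot = 1000, seed = 1) {
  v <- auc_values
  stopifnot(all(is.finite(v)))
  if (sd(v) == 0) {
    tau <- mean(v)
    return(list(threshold = tau, rule = "degenerate", active = v > tau,
                modality = "unimodal", dip = list(D = NA_real_, p = 1)))
  }
  if (is.null(dip)) dip <- dip_test(v, n_boot = n_boot, seed = seed)
  if (dip$p >= alpha) {
    tau <- mean(v) + 2 * sd(v)
    return(list(threshold = tau, rule = "mean+2sd", active = v > tau,
                modality = "unimodal", dip = dip))
  }
  h <- bandwidth %||% bw.nrd0(v)
  den <- density(v, bw = h, n = 512, from = min(v) - 3 * h, to = max(v) + 3 * h)
  y <- den$y
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(is_max) < 2) {
    warning("bimodal dip call but < 2 density peaks; falling back to mean+2sd")
    tau <- mean(v) + 2 * sd(v)
    return(list(threshold = tau, rule = "mean+2sd", active = v > tau,
                modality = "bimodal", dip = dip))
  }
  peaks <- is_max[order(-y[is_max])][1:2]
  lo <- min(peaks); hi <- max(peaks)
  inner <- (lo + 1L):(hi - 1L)
  tau <- den$x[inner[which.min(y[inner])]]
  list(threshold = tau, rule = "kde-trough", active = v > tau,
       modality = "bimodal", dip = dip)
}

jaccard_dist <- function(M) {
  # M: items x features binary matrix
  inter <- tcrossprod(M)
  sizes <- rowSums(M)
  un <- outer(sizes, sizes, "+") - inter
  J <- 1 - inter / ifelse(un > 0, un, 1)
  J[un == 0] <- 0
  stats::as.dist(J)
}

#' Binarize a full AUC matrix and cluster the result
#'
#' Runs [dip_test()] and [binarize_regulon()] per regulon, drops regulons
#' active in fewer than `min_active_frac` of the cells, and clusters the
#' remaining boolean matrix on both axes (Jaccard distance, average
#' linkage); row/column orders are recorded for heatmap display.
#'
#' @param auc An `auc_matrix` from [auc_score()].
#' @param alpha Dip significance level (default 0.05).
#' @param min_active_frac Minimum active-cell fraction (default 0.01).
#' @param bandwidth Optional fixed KDE bandwidth.
#' @param n_boot,seed Dip bootstrap parameters.
#' @return List with `report` (per-regulon data.frame: D, p, modality,
#'   threshold, rule, active_fraction, retained), `binary` (retained
#'   regulons x cells logical matrix), `row_order`, `col_order`.
#' @export
binarize_matrix <- function(auc, alpha = 0.05, min_active_frac = 0.01,
                            bandwidth = NULL, n_boot = 1000, seed = 1) {
  regs <- rownames(auc)
  nrr <- nrow(auc)
  report <- data.frame(
    regulon = regs, D = NA_real_, p = NA_real_,
    modality = NA_character_, threshold = NA_real_, rule = NA_character_,
    active_fraction = NA_real_, retained = FALSE, stringsAsFactors = FALSE
  )
  binary <- matrix(FALSE, nrr, ncol(auc), dimnames = dimnames(auc))
  for (i in seq_len(nrr)) {
    v <- auc[i, ]
    if (anyNA(v) || any(!is.finite(v))) next     # unresolvable regulon
    dip <- if (sd(v) == 0 || length(unique(v)) < 4) NULL else {
      dip_test(v, n_boot = n_boot, seed = seed)
    }
    bz <- if (is.null(dip) && sd(v) > 0 && length(unique(v)) < 4) {
      # too few distinct values for the dip test: treat as unimodal
      list(threshold = mean(v) + 2 * sd(v), rule = "mean+2sd",
           active = v > mean(v) + 2 * sd(v), modality = "unimodal",
           dip = list(D = NA_real_, p = 1))
    } else {
      binarize_regulon(v, dip = dip, alpha = alpha, bandwidth = bandwidth,
                       n_boot = n_boot, seed = seed)
    }
    report$D[i] <- bz$dip$D
    report$p[i] <- bz$dip$p
    report$modality[i] <- bz$modality
    report$threshold[i] <- bz$threshold
    report$rule[i] <- bz$rule
    report$active_fraction[i] <- mean(bz$active)
    binary[i, ] <- bz$active
  }
  report$retained <- !is.na(report$active_fraction) &
    report$active_fraction >= min_active_frac
  binary <- binary[report$retained, , drop = FALSE]
  if (nrow(binary) == 0) {
    warning("no regulon is active in at least ",
            format(100 * min_active_frac), "% of cells")
    return(list(report = report, binary = binary,
                row_order = integer(0), col_order = integer(0)))
  }
  row_order <- if (nrow(binary) >= 2) {
    hclust(jaccard_dist(binary * 1), method = "average")$order
  } else 1L
  col_order <- if (ncol(binary) >= 2 && nrow(binary) >= 1) {
    hclust(jaccard_dist(t(binary * 1)), method = "average")$order
  } else seq_len(ncol(binary))
  list(report = report, binary = binary, row_order = row_order,
       col_order = col_order)
}
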
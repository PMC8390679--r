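#' Log-normalize and z-scale expression (heatmap-style values)
#'
#' Computes `y_gc = ln(1 + scale_total * x_gc / N_c)` followed by per-gene
#' z-scaling across cells (zero-variance genes map to 0). These values are
#' used only for heatmap-style displays, never for testing.
#'
#' @param m A [umi_matrix] with positive cell totals.
#' @param scale_total Per-cell total after normalization (default 10 000).
#' @param scale If `FALSE`, return the log-normalized values without
#'   z-scaling.
#' @return A dense genes x cells matrix.
#' @export
log_normalize_scale <- function(m, scale_total = 10000, scale = TRUE) {
  stopifnot(inherits(m, "umi_matrix"))
  N <- cell_totals(m)
  if (any(N == 0)) stop("cells with zero total counts; run QC first")
  y <- as.matrix(m$counts %*% Matrix::Diagonal(x = scale_total / N))
  colnames(y) <- barcodes(m)
  y <- log1p(y)
  if (!scale) return(y)
  mu <- rowMeans(y)
  s <- apply(y, 1, sd)
  z <- (y - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Fit the regularized negative-binomial offset model
#'
#' Models expected counts as `mu_gc = N_c * p_g` where `p_g` is the gene's
#' share of the grand total (an offset/proportionality model). The per-gene
#' inverse-dispersion `theta_g` is estimated by maximum likelihood with the
#' means held fixed, bounded to `[0.01, 1e6]`, then regularized by
#' Gaussian-kernel regression of `log10(theta)` on `log10(gene mean)`
#' (Silverman's rule bandwidth unless given). Genes with zero totals are
#' excluded (their residuals are defined as 0).
#'
#' @param m A filtered [umi_matrix] with at least 2 cells.
#' @param bandwidth Kernel bandwidth on the log10 gene-mean axis (default
#'   Silverman's rule).
#' @param theta_bounds Lower/upper bounds for the raw MLE.
#' @param max_cells_fit If the matrix has more cells, dispersion is estimated
#'   on a seeded random subset of this many cells (the offset means use all
#'   cells); keeps the fit affordable without changing the model.
#' @param seed Seed for the cell subsample.
#' @return An `nb_fit` list: `p` (expected fractions), `theta_raw`,
#'   `theta` (regularized), `clip_bound` (`sqrt(n_cells)`), `gene_mean`,
#'   `n_cells`.
#' @export
fit_nb_model <- function(m, bandwidth = NULL, theta_bounds = c(0.01, 1e6),
                         max_cells_fit = 2000, seed = 1) {
  stopifnot(inherits(m, "umi_matrix"), n_cells(m) >= 2)
  x <- m$counts
  N <- Matrix::colSums(x)
  tot <- Matrix::rowSums(x)
  p <- as.numeric(tot) / sum(tot)
  names(p) <- rownames(x)
  use <- seq_len(ncol(x))
  if (ncol(x) > max_cells_fit) {
    use <- with_seed(seed, sort(sample.int(ncol(x), max_cells_fit)))
  }
  xs <- as.matrix(x[, use, drop = FALSE])
  Ns <- N[use]
  lo <- log(theta_bounds[1]); hi <- log(theta_bounds[2])
  theta_raw <- rep(NA_real_, nrow(x))
  for (g in seq_len(nrow(x))) {
    if (tot[g] == 0) next
    mu <- Ns * p[g]
    y <- xs[g, ]
    nll <- function(lt) -sum(dnbinom(y, size = exp(lt), mu = mu, log = TRUE))
    opt <- optimize(nll, c(lo, hi), tol = 1e-3)
    th <- exp(opt$minimum)
    # snap to the bounds when the optimum sits against them (Poisson limit)
    if (opt$minimum > hi - 1e-2 && nll(hi) <= opt$objective + 1e-8) th <- theta_bounds[2]
    if (opt$minimum < lo + 1e-2 && nll(lo) <= opt$objective + 1e-8) th <- theta_bounds[1]
    theta_raw[g] <- th
  }
  gene_mean <- as.numeric(tot) / ncol(x)
  fitted_idx <- which(!is.na(theta_raw))
  lx <- log10(gene_mean[fitted_idx])
  ly <- log10(theta_raw[fitted_idx])
  if (is.null(bandwidth)) bandwidth <- max(bw.nrd0(lx), 1e-3)
  theta <- rep(NA_real_, nrow(x))
  # Nadaraya-Watson smoother evaluated at each gene's own abscissa
  sm <- vapply(lx, function(x0) {
    w <- exp(-0.5 * ((lx - x0) / bandwidth)^2)
    sum(w * ly) / sum(w)
  }, numeric(1))
  theta[fitted_idx] <- pmin(pmax(10^sm, theta_bounds[1]), theta_bounds[2])
  names(theta) <- names(theta_raw) <- rownames(x)
  structure(list(
    p = p, theta_raw = theta_raw, theta = theta,
    clip_bound = sqrt(ncol(x)), gene_mean = gene_mean,
    n_cells = ncol(x), bandwidth = bandwidth
  ), class = "nb_fit")
}

#' Pearson residuals under the regularized NB model
#'
#' `z_gc = (x_gc - mu_gc) / sqrt(mu_gc + mu_gc^2 / theta_g)` with
#' `mu_gc = N_c p_g`, clipped to `[-C, C]` with `C = sqrt(n_cells)`.
#' Genes excluded from the fit (zero totals) get all-zero residuals.
#'
#' @param m The [umi_matrix] the fit was computed on.
#' @param fit An `nb_fit`.
#' @return A dense genes x cells `residual_matrix` (clip bound in
#'   `attr(, "clip_bound")`).
#' @export
pearson_residuals <- function(m, fit) {
  stopifnot(inherits(m, "umi_matrix"), inherits(fit, "nb_fit"))
  x <- as.matrix(m$counts)
  N <- cell_totals(m)
  mu <- outer(fit$p[rownames(x)], N)
  th <- fit$theta[rownames(x)]
  denom <- sqrt(mu + mu^2 / th)
  z <- (x - mu) / denom
  z[!is.finite(z)] <- 0
  C <- fit$clip_bound
  z <- pmin(pmax(z, -C), C)
  dimnames(z) <- dimnames(x)
  attr(z, "clip_bound") <- C
  class(z) <- c("residual_matrix", class(z))
  z
}

#' Welch's two-sample t test (two-tailed)
#'
#' Direct Welch statistic with Satterthwaite degrees of freedom. Degenerate
#' inputs: equal-mean zero-variance groups give `t = 0, p = 1`;
#' different-mean zero-variance groups give the smallest representable p.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  va <- var(a); vb <- var(b)
  d <- mean(a) - mean(b)
  se2 <- va / length(a) + vb / length(b)
  if (se2 == 0) {
    if (d == 0) return(list(t = 0, df = Inf, p = 1))
    return(list(t = sign(d) * Inf, df = Inf, p = .Machine$double.xmin))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = max(p, .Machine$double.xmin))
}

# Row-wise Welch t for a genes x cells residual matrix split into two groups.
welch_t_rows <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  d <- mA - mB
  se2 <- vA / nA + vB / nB
  t <- ifelse(se2 > 0, d / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)),
               Inf)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t), df),
              ifelse(d == 0, 1, .Machine$double.xmin))
  p <- pmax(p, .Machine$double.xmin)
  # zero-variance unequal means: deterministic extreme call
  t[se2 == 0 & d != 0] <- sign(d[se2 == 0 & d != 0]) * Inf
  data.frame(mean_diff = d, t = t, df = df, p = p)
}

#' Empirical null band from random cell subsets
#'
#' For each of `n_partitions` seeded random partitions of the pooled cells
#' into groups of sizes `(nA, nB)`, computes the per-gene absolute mean
#' residual difference; the band `B` is the given percentile (default 99.9)
#' of the pooled genes x partitions absolute differences. This is the gray
#' band drawn on volcano plots: an effect-size floor below which observed
#' differences are indistinguishable from random splits.
#'
#' @param residuals A genes x cells residual matrix of the pooled cells.
#' @param group_sizes Integer vector `c(nA, nB)`; both >= 2 and summing to at
#'   most the number of cells.
#' @param n_partitions Number of random partitions (default 100).
#' @param percentile Percentile of pooled absolute differences (default 99.9).
#' @param seed Seed for the partitions.
#' @return A `null_band` list: `band`, `n_partitions`, `percentile`, `seed`.
#' @export
permutation_null_band <- function(residuals, group_sizes, n_partitions = 100,
                                  percentile = 99.9, seed = 1) {
  nA <- group_sizes[1]; nB <- group_sizes[2]
  if (nA < 2 || nB < 2) stop("both group sizes must be >= 2")
  nc <- ncol(residuals)
  if (nA + nB > nc) stop("group sizes exceed number of cells")
  diffs <- with_seed(seed, {
    vapply(seq_len(n_partitions), function(i) {
      idx <- sample.int(nc, nA + nB)
      a <- idx[seq_len(nA)]
      b <- idx[nA + seq_len(nB)]
      abs(rowMeans(residuals[, a, drop = FALSE]) -
            rowMeans(residuals[, b, drop = FALSE]))
    }, numeric(nrow(residuals)))
  })
  structure(list(
    band = as.numeric(quantile(diffs, percentile / 100, names = FALSE)),
    n_partitions = n_partitions, percentile = percentile, seed = seed
  ), class = "null_band")
}

#' Benjamini-Hochberg adjusted p values
#'
#' @param p Vector of p values in `[0, 1]`.
#' @return Step-up adjusted q values (monotone in rank).
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Differential expression configuration
#'
#' @param fdr FDR cutoff on BH-adjusted p (default 0.01).
#' @param percentile Null-band percentile (default 99.9).
#' @param n_partitions Random partitions for the band (default 100).
#' @param seed Seed for the band partitions.
#' @param max_cells_fit Passed to [fit_nb_model()].
#' @export
de_config <- function(fdr = 0.01, percentile = 99.9, n_partitions = 100,
                      seed = 1, max_cells_fit = 2000) {
  structure(list(fdr = fdr, percentile = percentile,
                 n_partitions = n_partitions, seed = seed,
                 max_cells_fit = max_cells_fit), class = "de_config")
}

#' Run the Pearson-residual differential expression pipeline
#'
#' Fits the regularized NB model on the two groups' cells, computes clipped
#' Pearson residuals, per-gene two-tailed Welch t tests, BH-adjusted q
#' values, and the random-subset null band. A gene is significant iff
#' `q < fdr` AND `|mean difference| > band`. The table is sorted by p
#' (ties by decreasing `|t|`).
#'
#' @param m A [umi_matrix] containing both groups.
#' @param group_a,group_b Disjoint nonempty barcode vectors. Mean differences
#'   are `group_a - group_b`.
#' @param config A [de_config()].
#' @return A `de_table` data.frame: gene, mean_diff, t, df, p, q,
#'   neg_log10_p, band, significant; the band and config are attached as
#'   attributes.
#' @export
run_de <- function(m, group_a, group_b, config = de_config()) {
  stopifnot(inherits(m, "umi_matrix"))
  if (!length(group_a) || !length(group_b)) stop("empty group")
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  missing <- setdiff(c(group_a, group_b), barcodes(m))
  if (length(missing)) stop("unknown barcodes: ", paste(head(missing), collapse = ", "))
  sub <- umi_subset(m, cells = c(group_a, group_b))
  fit <- fit_nb_model(sub, max_cells_fit = config$max_cells_fit,
                      seed = derive_seed(config$seed, "fit"))
  z <- pearson_residuals(sub, fit)
  A <- z[, group_a, drop = FALSE]
  B <- z[, group_b, drop = FALSE]
  tt <- welch_t_rows(A, B)
  tt$q <- bh_fdr(tt$p)
  band <- permutation_null_band(z, c(length(group_a), length(group_b)),
                                n_partitions = config$n_partitions,
                                percentile = config$percentile,
                                seed = derive_seed(config$seed, "band"))
  out <- data.frame(
    gene = rownames(z), mean_diff = tt$mean_diff, t = tt$t, df = tt$df,
    p = tt$p, q = tt$q, neg_log10_p = -log10(tt$p), band = band$band,
    significant = tt$q < config$fdr & abs(tt$mean_diff) > band$band,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, -abs(out$t)), ]
  rownames(out) <- NULL
  attr(out, "null_band") <- band
  attr(out, "config") <- config
  class(out) <- c("de_table", class(out))
  out
}
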
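#' Graph-geodesic pseudotime
#'
#' Pseudotime is the shortest-path distance from a root cell along the kNN
#' graph (edge weights = Euclidean PC-space lengths), min-max scaled to
#' `[0, 1]`. Cells outside the root's connected component get `NA` and are
#' flagged.
#'
#' @param emb An `embedding` from [pca_knn_embed()].
#' @param root Root barcode (pseudotime 0).
#' @return A `pseudotime_result` list: `pseudotime` (named numeric),
#'   `root`, `unreachable` (barcodes).
#' @export
graph_pseudotime <- function(emb, root) {
  stopifnot(inherits(emb, "embedding"))
  g <- emb$graph
  if (!root %in% igraph::V(g)$name) stop("root barcode not in graph: ", root)
  d <- as.numeric(igraph::distances(g, v = root, weights = igraph::E(g)$dist))
  names(d) <- igraph::V(g)$name
  unreachable <- names(d)[!is.finite(d)]
  fin <- is.finite(d)
  rng <- range(d[fin])
  pt <- rep(NA_real_, length(d)); names(pt) <- names(d)
  pt[fin] <- if (diff(rng) > 0) (d[fin] - rng[1]) / diff(rng) else 0
  structure(list(pseudotime = pt, root = root, unreachable = unreachable),
            class = "pseudotime_result")
}

#' Pick a default pseudotime root
#'
#' The cell with the highest naive-pluripotency signature score.
#'
#' @param m A [umi_matrix] restricted to the trajectory's cells.
#' @param naive_genes Gene ids of the naive signature.
#' @return A barcode.
#' @export
select_root <- function(m, naive_genes) {
  s <- score_signature(m, naive_genes)
  names(which.max(s))
}

moran_weight_matrix <- function(graph) {
  W <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  W <- (W + Matrix::t(W)) > 0     # symmetrized unit weights
  W <- as(W, "dMatrix")
  Matrix::diag(W) <- 0
  W
}

moran_stat <- function(y, W, S0 = sum(W)) {
  z <- y - mean(y)
  ss <- sum(z^2)
  if (ss == 0) return(NA_real_)
  as.numeric(length(y) / S0 * (z %*% (W %*% z)) / ss)
}

#' Moran's I on a cell-neighbourhood graph
#'
#' `I = n / S0 * sum_ij w_ij z_i z_j / sum_i z_i^2` with symmetrized unit kNN
#' adjacency weights. The p value is one-sided (positive autocorrelation):
#' with `n_permutations > 0`, by seeded label permutation
#' (`p = (1 + #\{I_perm >= I\}) / (n_permutations + 1)`); with
#' `n_permutations = 0`, from the closed-form randomization mean and variance
#' (normal approximation).
#'
#' @param y Per-cell numeric values (constant input gives an undefined flag
#'   and p = 1).
#' @param graph An igraph kNN graph (or an `embedding`).
#' @param n_permutations Number of permutations (default 999; 0 = analytic).
#' @param seed Permutation seed.
#' @return List with `I`, `z`, `p`, `undefined`.
#' @export
moran_i <- function(y, graph, n_permutations = 999, seed = 1) {
  if (inherits(graph, "embedding")) graph <- graph$graph
  W <- moran_weight_matrix(graph)
  n <- length(y)
  stopifnot(n == nrow(W))
  if (var(y) == 0) {
    return(list(I = NA_real_, z = NA_real_, p = 1, undefined = TRUE))
  }
  S0 <- sum(W)
  I <- moran_stat(y, W, S0)
  an <- moran_moments(y, W, S0)
  zsc <- (I - an$mean) / sqrt(an$var)
  if (n_permutations > 0) {
    perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
      moran_stat(sample(y), W, S0)
    }, numeric(1)))
    p <- (1 + sum(perm >= I)) / (n_permutations + 1)
  } else {
    p <- pnorm(zsc, lower.tail = FALSE)
  }
  list(I = I, z = zsc, p = p, undefined = FALSE)
}

# Closed-form mean/variance of I under the randomization assumption.
moran_moments <- function(y, W, S0 = sum(W)) {
  n <- length(y)
  z <- y - mean(y)
  S1 <- sum((W + Matrix::t(W))^2) / 2
  rs <- Matrix::rowSums(W); cs <- Matrix::colSums(W)
  S2 <- sum((rs + cs)^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  EI <- -1 / (n - 1)
  EI2 <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
            b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2)
  list(mean = EI, var = EI2 - EI^2)
}

# Moran's I for every row of a dense features x cells matrix in one pass,
# with analytic z and one-sided p.
moran_i_all <- function(mat, graph) {
  if (inherits(graph, "embedding")) graph <- graph$graph
  W <- moran_weight_matrix(graph)
  n <- ncol(mat)
  S0 <- sum(W)
  Z <- mat - rowMeans(mat)
  ss <- rowSums(Z^2)
  num <- rowSums(as.matrix(Z %*% W) * Z)
  I <- ifelse(ss > 0, n / S0 * num / ss, NA_real_)
  S1 <- sum((W + Matrix::t(W))^2) / 2
  rs <- Matrix::rowSums(W); cs <- Matrix::colSums(W)
  S2 <- sum((rs + cs)^2)
  b2 <- ifelse(ss > 0, n * rowSums(Z^4) / ss^2, NA_real_)
  EI <- -1 / (n - 1)
  EI2 <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
            b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2)
  v <- EI2 - EI^2
  zsc <- (I - EI) / sqrt(v)
  data.frame(
    gene = rownames(mat), I = I, z = zsc,
    p = pnorm(zsc, lower.tail = FALSE),
    undefined = !is.finite(I), stringsAsFactors = FALSE
  )
}

#' Rank genes along pseudotime and cluster their dynamics
#'
#' Ranks genes by Moran's I on the kNN graph (computed on log-normalized
#' expression), selects the top `top_n`, averages each selected gene's
#' expression in `n_bins` equal-width pseudotime bins (empty bins linearly
#' interpolated), z-scales the profiles, and cuts an average-linkage
#' Euclidean hierarchical clustering at k = 2 into `"down"` and `"up"`
#' dynamics groups (by the sign of the centroid's trend).
#'
#' @param m A [umi_matrix] of the trajectory's cells.
#' @param pt A `pseudotime_result` covering those cells.
#' @param graph igraph kNN graph (or `embedding`) on the same cells.
#' @param top_n Genes to select (default 100); if fewer genes have defined
#'   Moran's I, all are returned with a warning.
#' @param n_bins Pseudotime bins (default 20).
#' @return List with `moran` (per-gene I, z, p, rank, sorted), `clusters`
#'   (named `"down"`/`"up"` per selected gene), `profiles` (selected genes x
#'   bins z-scaled matrix), `bin_centers`.
#' @export
rank_and_cluster_dynamics <- function(m, pt, graph, top_n = 100, n_bins = 20) {
  stopifnot(inherits(m, "umi_matrix"), inherits(pt, "pseudotime_result"))
  bcs <- barcodes(m)
  tvals <- pt$pseudotime[bcs]
  keep <- !is.na(tvals)
  y <- log_normalize_scale(umi_subset(m, cells = bcs[keep]), scale = FALSE)
  if (inherits(graph, "embedding")) graph <- graph$graph
  g <- igraph::induced_subgraph(graph, bcs[keep])
  y <- y[, igraph::V(g)$name, drop = FALSE]
  mor <- moran_i_all(y, g)
  mor <- mor[order(-mor$I, mor$gene), ]
  mor$rank <- ifelse(is.finite(mor$I), seq_len(nrow(mor)), NA_integer_)
  defined <- mor$gene[is.finite(mor$I)]
  if (length(defined) < top_n) {
    warning(sprintf("only %d genes with defined Moran's I (top_n = %d)",
                    length(defined), top_n))
    top_n <- length(defined)
  }
  sel <- mor$gene[seq_len(top_n)]
  tt <- pt$pseudotime[colnames(y)]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(tt, breaks, include.lowest = TRUE, labels = FALSE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  prof <- matrix(NA_real_, length(sel), n_bins,
                 dimnames = list(sel, sprintf("bin%02d", seq_len(n_bins))))
  for (b in seq_len(n_bins)) {
    idx <- which(bin == b)
    if (length(idx)) prof[, b] <- rowMeans(y[sel, idx, drop = FALSE])
  }
  for (gi in seq_len(nrow(prof))) {
    v <- prof[gi, ]
    if (anyNA(v)) {
      prof[gi, ] <- approx(centers[!is.na(v)], v[!is.na(v)], xout = centers,
                           rule = 2)$y
    }
  }
  mu <- rowMeans(prof); s <- apply(prof, 1, sd)
  prof <- (prof - mu) / ifelse(s > 0, s, 1)
  clusters <- if (nrow(prof) >= 2) {
    hc <- hclust(dist(prof), method = "average")
    k <- cutree(hc, k = 2)
    lab <- vapply(1:2, function(ki) {
      cen <- colMeans(prof[k == ki, , drop = FALSE])
      if (cor(cen, seq_along(cen)) < 0) "down" else "up"
    }, character(1))
    if (lab[1] == lab[2]) lab <- c("down", "up")  # degenerate tie-break
    setNames(lab[k], rownames(prof))
  } else {
    setNames(rep("up", nrow(prof)), rownames(prof))
  }
  list(moran = mor, clusters = clusters, profiles = prof,
       bin_centers = centers)
}
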
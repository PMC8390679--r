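#' PCA embedding and kNN graph
#'
#' PCA on cells (centered residuals), with a fixed sign convention (the
#' largest-magnitude loading of each component is positive) for
#' reproducibility, followed by a symmetrized unit-weight k-nearest-neighbour
#' graph (Euclidean distance in PC space, no self loops). Edge Euclidean
#' lengths are stored for geodesic pseudotime.
#'
#' @param residuals A genes x cells residual matrix (see
#'   [pearson_residuals()]), or any numeric genes x cells matrix.
#' @param n_dims Number of principal components (default 30).
#' @param k Neighbours per cell (default 15).
#' @param seed Unused source of randomness placeholder (PCA and kNN are
#'   deterministic); kept for interface stability.
#' @return An `embedding` list: `coords` (cells x dims), `graph` (igraph,
#'   undirected, edge attribute `dist`), `knn` (cells x k neighbour index
#'   matrix), `var_explained`, `k`.
#' @export
pca_knn_embed <- function(residuals, n_dims = 30, k = 15, seed = 1) {
  X <- t(unclass(residuals))          # cells x genes
  nc <- nrow(X)
  if (n_dims >= nc) stop("n_dims must be smaller than the number of cells")
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_dims)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, "*")
  rownames(coords) <- rownames(X)
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  k_eff <- min(k, nc - 1)
  knn <- t(apply(D, 1, function(d) order(d)[seq_len(k_eff)]))
  from <- rep(seq_len(nc), k_eff)
  to <- as.vector(knn)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- rownames(coords)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  igraph::E(g)$dist <- D[cbind(ends[, 1], ends[, 2])]
  structure(list(
    coords = coords, graph = g, knn = knn,
    var_explained = pc$sdev[seq_len(n_dims)]^2 / sum(pc$sdev^2),
    k = k_eff
  ), class = "embedding")
}

#' Cluster cells on the kNN graph
#'
#' Greedy modularity maximization (agglomerative merge tree) on the
#' symmetrized unit-weight kNN graph; fully deterministic. `resolution` is a
#' coarseness knob applied to the merge tree: with the modularity-optimal
#' partition having `K` communities, the tree is cut at
#' `max(1, round(resolution * K))` communities (never below the number of
#' connected components), so smaller values give fewer, larger clusters.
#'
#' @param emb An `embedding` from [pca_knn_embed()].
#' @param resolution Coarseness multiplier (default 1.0 = modularity-optimal
#'   cut).
#' @param seed Kept for interface stability (the algorithm is
#'   deterministic).
#' @return A `cluster_assignment` list: `labels` (named by barcode, factor
#'   `"C1"`, `"C2"`, ...), `merged` (map, initially identity), `method`.
#' @export
cluster_graph <- function(emb, resolution = 1.0, seed = 1) {
  stopifnot(inherits(emb, "embedding"))
  g <- emb$graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  cl <- igraph::cluster_fast_greedy(g)
  mem <- igraph::membership(cl)
  if (resolution != 1.0) {
    K <- length(unique(mem))
    n_comp <- igraph::count_components(g)
    target <- min(max(n_comp, round(resolution * K), 1), igraph::vcount(g))
    mem <- suppressWarnings(igraph::cut_at(cl, no = target))
    names(mem) <- igraph::V(g)$name
  }
  # relabel by decreasing size for stable, readable ids
  sizes <- sort(table(mem), decreasing = TRUE)
  relab <- setNames(sprintf("C%d", seq_along(sizes)), names(sizes))
  labels <- factor(unname(relab[as.character(mem)]),
                   levels = sprintf("C%d", seq_along(sizes)))
  names(labels) <- igraph::V(g)$name
  structure(list(
    labels = labels,
    merged = setNames(levels(labels), levels(labels)),
    method = list(algorithm = "greedy-modularity", resolution = resolution,
                  seed = seed)
  ), class = "cluster_assignment")
}

#' Manually merge clusters
#'
#' Records a manual recombination of unsupervised clusters; both the original
#' and the merged labels are retained.
#'
#' @param assign A `cluster_assignment`.
#' @param merge_map Named character vector `c(old = new, ...)`; keys must be
#'   existing cluster ids.
#' @return The updated `cluster_assignment` with `labels` merged and
#'   `original_labels` kept.
#' @export
merge_clusters <- function(assign, merge_map) {
  stopifnot(inherits(assign, "cluster_assignment"))
  if (!length(merge_map)) return(assign)
  bad <- setdiff(names(merge_map), levels(assign$labels))
  if (length(bad)) stop("unknown cluster id(s): ", paste(bad, collapse = ", "))
  orig <- assign$original_labels %||% assign$labels
  map <- assign$merged
  map[names(merge_map)] <- merge_map
  new_labels <- factor(unname(map[as.character(assign$labels)]))
  names(new_labels) <- names(assign$labels)
  assign$original_labels <- orig
  assign$labels <- new_labels
  assign$merged <- map
  assign
}

#' Annotate clusters by marker signature score
#'
#' Each cluster receives the name of the marker set with the highest mean
#' per-cell signature score ([score_signature()]) among its cells; ties are
#' broken alphabetically and flagged.
#'
#' @param m A [umi_matrix].
#' @param assign A `cluster_assignment`.
#' @param marker_sets Named list of marker gene sets.
#' @return Named character vector cluster -> type, with attributes `tied`
#'   (logical per cluster) and `scores` (cluster x set mean-score matrix).
#' @export
annotate_clusters <- function(m, assign, marker_sets) {
  stopifnot(inherits(assign, "cluster_assignment"),
            is.list(marker_sets), length(marker_sets) > 0)
  S <- score_signatures(m, marker_sets)   # sets x cells
  labels <- assign$labels[barcodes(m)]
  cl <- levels(assign$labels)
  means <- vapply(cl, function(cc) {
    rowMeans(S[, labels == cc, drop = FALSE])
  }, numeric(nrow(S)))
  means <- t(means)  # cluster x set
  ann <- character(length(cl)); tied <- logical(length(cl))
  set_names <- sort(rownames(S))
  for (i in seq_along(cl)) {
    v <- means[i, ]
    best <- names(v)[v == max(v)]
    if (max(v) == 0) {
      ann[i] <- "unassigned"; tied[i] <- TRUE
    } else {
      ann[i] <- sort(best)[1]
      tied[i] <- length(best) > 1
    }
  }
  names(ann) <- cl; names(tied) <- cl
  if (any(tied)) warning("tied or unassigned cluster annotation(s): ",
                         paste(cl[tied], collapse = ", "))
  attr(ann, "tied") <- tied
  attr(ann, "scores") <- means
  ann
}

#' Per-condition cell-type composition
#'
#' Counts and within-condition fractions of each label per condition; with
#' exactly two conditions a difference column (first minus second, `wt - mt`
#' when those names are present) is included.
#'
#' @param labels Named (by barcode) character/factor vector of cluster or
#'   cell-type labels.
#' @param conditions Named (by barcode) character vector of conditions.
#' @return A `composition_table` data.frame: condition, label, n, fraction
#'   (fractions per condition sum to 1); the difference table is in
#'   `attr(, "difference")`.
#' @export
composition_by_condition <- function(labels, conditions) {
  bcs <- intersect(names(labels), names(conditions))
  if (!length(bcs)) stop("no shared barcodes between labels and conditions")
  if (anyNA(conditions[bcs])) stop("every barcode needs a condition")
  tab <- table(condition = as.character(conditions[bcs]),
               label = as.character(labels[bcs]))
  frac <- prop.table(tab, margin = 1)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  out$fraction <- as.data.frame(frac)$Freq
  out <- out[order(out$condition, out$label), ]
  rownames(out) <- NULL
  conds <- rownames(tab)
  if (length(conds) == 2) {
    ord <- if (all(c("wt", "mt") %in% conds)) c("wt", "mt") else conds
    diff <- data.frame(
      label = colnames(frac),
      difference = as.numeric(frac[ord[1], ] - frac[ord[2], ]),
      stringsAsFactors = FALSE
    )
    attr(out, "difference") <- diff
    attr(out, "difference_order") <- ord
  }
  class(out) <- c("composition_table", class(out))
  out
}
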
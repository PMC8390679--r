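path_embedding <- function() {
  g <- igraph::make_graph(~ A - B, B - C)
  igraph::E(g)$dist <- c(1, 1)
  structure(list(graph = g), class = "embedding")
}

test_that("geodesic pseudotime on a path graph is 0, 0.5, 1", {
  pt <- graph_pseudotime(path_embedding(), "A")
  expect_equal(unname(pt$pseudotime[c("A", "B", "C")]), c(0, 0.5, 1))
  expect_equal(pt$root, "A")
  expect_error(graph_pseudotime(path_embedding(), "Z"), "root")
})

test_that("cells outside the root component are flagged unreachable", {
  g <- igraph::make_graph(~ A - B) + igraph::make_graph(~ C - D)
  igraph::E(g)$dist <- c(1, 1)
  emb <- structure(list(graph = g), class = "embedding")
  pt <- graph_pseudotime(emb, "A")
  expect_setequal(pt$unreachable, c("C", "D"))
  expect_true(all(is.na(pt$pseudotime[c("C", "D")])))
})

test_that("Moran's I on a complete graph equals -1/(n-1) exactly", {
  for (n in c(5, 8)) {
    g <- igraph::make_full_graph(n)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    y <- rnorm(n)
    expect_equal(moran_i(y, g, n_permutations = 0)$I, -1 / (n - 1),
                 tolerance = 1e-12)
  }
})

test_that("Moran's I matches the double-loop oracle", {
  set.seed(11)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(10, 0.4)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("v", 1:10)
    y <- rnorm(10)
    W <- as.matrix(igraph::as_adjacency_matrix(g))
    W <- 1 * ((W + t(W)) > 0); diag(W) <- 0
    z <- y - mean(y)
    num <- 0
    for (a in 1:10) for (b in 1:10) num <- num + W[a, b] * z[a] * z[b]
    ref <- 10 / sum(W) * num / sum(z^2)
    expect_equal(moran_i(y, g, n_permutations = 0)$I, ref, tolerance = 1e-12)
  }
})

test_that("constant input gives an undefined flag and p = 1", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- paste0("v", 1:6)
  res <- moran_i(rep(2, 6), g)
  expect_true(res$undefined)
  expect_equal(res$p, 1)
})

test_that("permutation p values are super-uniform under the null", {
  set.seed(23)
  g <- igraph::sample_gnp(25, 0.2)
  igraph::V(g)$name <- paste0("v", 1:25)
  ps <- vapply(1:150, function(i) {
    moran_i(rnorm(25), g, n_permutations = 199, seed = i)$p
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    se <- sqrt(alpha * (1 - alpha) / length(ps))
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
  }
})

test_that("permutation and analytic p agree for a strong signal", {
  set.seed(9)
  # smooth signal along a ring: strongly positive autocorrelation
  g <- igraph::make_ring(40)
  igraph::V(g)$name <- paste0("v", 1:40)
  y <- sin(seq(0, 2 * pi, length.out = 40)) + rnorm(40, sd = 0.1)
  perm <- moran_i(y, g, n_permutations = 999, seed = 2)
  ana <- moran_i(y, g, n_permutations = 0)
  expect_lt(perm$p, 0.01)
  expect_lt(ana$p, 0.01)
  expect_equal(perm$I, ana$I)
})

test_that("pseudotime-dependent genes rank high and split into up/down", {
  proc <- get_small_processed()
  sim <- proc$sim
  tr <- sim$truth
  epi <- intersect(names(tr$cell_type)[tr$cell_type == "Epi"],
                   barcodes(proc$umi))
  sub <- umi_subset(proc$umi, cells = epi)
  emb <- pca_knn_embed(proc$residuals[, epi], n_dims = 10, k = 15)
  root <- select_root(sub, tr$naive_genes)
  pt <- graph_pseudotime(emb, root)
  expect_equal(unname(pt$pseudotime[root]), 0)
  keep <- !is.na(pt$pseudotime[epi])
  rho <- cor(pt$pseudotime[epi][keep], tr$pseudotime[epi][keep],
             method = "spearman")
  expect_gt(rho, 0.8)

  res <- rank_and_cluster_dynamics(sub, pt, emb, top_n = 100)
  sel <- names(res$clusters)
  pt_genes <- c(tr$naive_genes, tr$primed_genes)
  expect_gte(length(intersect(sel, pt_genes)), 36)  # >= 90% of the 40
  naive_cl <- res$clusters[intersect(sel, tr$naive_genes)]
  primed_cl <- res$clusters[intersect(sel, tr$primed_genes)]
  expect_gte(mean(naive_cl == "down"), 0.9)
  expect_gte(mean(primed_cl == "up"), 0.9)
})

test_that("top_n larger than the defined gene count warns and returns all", {
  m <- toy_umi(matrix(rpois(5 * 30, 4), 5, 30))
  set.seed(1)
  coords <- matrix(rnorm(60), 30, 2,
                   dimnames = list(barcodes(m), NULL))
  emb <- pca_knn_embed(matrix(rnorm(5 * 30), 5, 30,
                              dimnames = list(gene_ids(m), barcodes(m))),
                       n_dims = 2, k = 3)
  pt <- graph_pseudotime(emb, barcodes(m)[1])
  expect_warning(
    res <- rank_and_cluster_dynamics(m, pt, emb, top_n = 100),
    "top_n"
  )
  expect_lte(length(res$clusters), 5)
})
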
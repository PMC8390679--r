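fake_embedding <- function(graph, coords = NULL) {
  structure(list(graph = graph, coords = coords, knn = NULL,
                 var_explained = NULL, k = NA), class = "embedding")
}

test_that("PCA separates two distinct populations on the first component", {
  set.seed(2)
  z <- cbind(matrix(rnorm(50 * 30, 0), 50), matrix(rnorm(50 * 30, 4), 50))
  colnames(z) <- sprintf("c%02d", 1:60)
  rownames(z) <- sprintf("g%02d", 1:50)
  emb <- pca_knn_embed(z, n_dims = 5, k = 5)
  lab <- rep(1:2, each = 30)
  sil <- cluster::silhouette(lab, dist(emb$coords[, 1, drop = FALSE]))
  expect_gt(mean(sil[, 3]), 0.5)
})

test_that("duplicate cells get identical coordinates", {
  set.seed(3)
  z <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(sprintf("g%d", 1:40), sprintf("c%d", 1:10)))
  z <- cbind(z, c11 = z[, "c3"])
  emb <- pca_knn_embed(z, n_dims = 3, k = 2)
  expect_equal(emb$coords["c3", ], emb$coords["c11", ], tolerance = 1e-10)
})

test_that("k = 1 on collinear points links nearest neighbours", {
  z <- matrix(c(0, 1, 3), nrow = 1,
              dimnames = list("g1", c("a", "b", "c")))
  z <- rbind(z, 0)  # second gene, constant
  rownames(z) <- c("g1", "g2")
  emb <- pca_knn_embed(z, n_dims = 1, k = 1)
  el <- igraph::as_edgelist(emb$graph)
  edges <- apply(el, 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(edges, c("a-b", "b-c"))  # c's nearest is b, a's is b
  expect_error(pca_knn_embed(z, n_dims = 3, k = 1), "n_dims")
})

test_that("two disconnected cliques yield exactly two clusters", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::V(g)$name <- sprintf("v%d", 1:10)
  cl <- cluster_graph(fake_embedding(g))
  expect_equal(nlevels(cl$labels), 2)
  expect_equal(length(unique(cl$labels[1:5])), 1)
  expect_equal(length(unique(cl$labels[6:10])), 1)
  # coarser resolution cannot go below the component count but never splits
  cl2 <- cluster_graph(fake_embedding(g), resolution = 0.01)
  expect_lte(nlevels(cl2$labels), nlevels(cl$labels))
  expect_error(cluster_graph(fake_embedding(igraph::make_empty_graph(0))),
               "empty")
})

test_that("cluster merging keeps originals and validates ids", {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4) +
    igraph::make_full_graph(4)
  igraph::V(g)$name <- sprintf("v%d", 1:12)
  cl <- cluster_graph(fake_embedding(g))
  expect_identical(merge_clusters(cl, setNames(character(0), character(0))),
                   cl)
  merged <- merge_clusters(cl, c(C2 = "C1"))
  expect_equal(nlevels(merged$labels), 2)
  expect_identical(unname(merged$original_labels), unname(cl$labels))
  expect_error(merge_clusters(cl, c(Z9 = "C1")), "unknown cluster")
})

test_that("clusters are annotated by the best-scoring marker set", {
  mat <- cbind(a1 = c(10, 0, 5), a2 = c(8, 1, 6), b1 = c(0, 9, 4),
               b2 = c(1, 10, 5))
  m <- toy_umi(mat, genes = c("mA", "mB", "x"))
  labels <- factor(c("C1", "C1", "C2", "C2"), levels = c("C1", "C2"))
  names(labels) <- colnames(mat)
  assign <- structure(list(labels = labels,
                           merged = c(C1 = "C1", C2 = "C2"),
                           method = list()), class = "cluster_assignment")
  ann <- annotate_clusters(m, assign, list(A = "mA", B = "mB"))
  expect_identical(as.character(ann), c("A", "B"))
  # identical marker sets under two names: alphabetical tie-break plus flag
  expect_warning(
    ann2 <- annotate_clusters(m, assign, list(Z = "mA", A = "mA")),
    "tied"
  )
  expect_identical(unname(ann2[1]), "A")
  # markers absent from the data: flagged unassigned
  expect_warning(
    ann3 <- annotate_clusters(m, assign, list(A = "absent1", B = "absent2")),
    "tied|unassigned"
  )
  expect_true(all(ann3 == "unassigned"))
})

test_that("composition fractions sum to 1 and ignore barcode order", {
  labels <- setNames(c("A", "A", "B", "A", "B"), paste0("c", 1:5))
  conds <- setNames(c("wt", "wt", "wt", "mt", "mt"), paste0("c", 1:5))
  comp <- composition_by_condition(labels, conds)
  for (cc in unique(comp$condition)) {
    expect_equal(sum(comp$fraction[comp$condition == cc]), 1)
  }
  set.seed(1)
  perm <- sample(5)
  comp2 <- composition_by_condition(labels[perm], conds)
  expect_equal(comp, comp2, ignore_attr = TRUE)
  diff <- attr(comp, "difference")
  expect_equal(diff$difference[diff$label == "A"], 2 / 3 - 1 / 2)
  one <- composition_by_condition(setNames("A", "c1"), setNames("wt", "c1"))
  expect_equal(one$fraction, 1)
})

test_that("unsupervised clusters recover the simulated populations", {
  proc <- get_small_processed()
  cl <- cluster_graph(proc$emb)
  truth <- proc$sim$truth$cell_type[names(cl$labels)]
  ari <- mclust::adjustedRandIndex(as.character(cl$labels), truth)
  expect_gt(ari, 0.8)
})
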
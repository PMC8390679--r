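# independent brute-force recovery-curve enumeration
auc_bruteforce <- function(counts, regulon_idx, k, rank_order) {
  hits <- cumsum(seq_along(rank_order) %in% match(regulon_idx, rank_order))
  sum(hits[seq_len(k)]) / sum(pmin(seq_len(k), length(regulon_idx)))
}

test_that("prefilter thresholds follow the 1%-of-cells rule", {
  set.seed(6)
  m <- toy_umi(matrix(rpois(5 * 100, 2), 5, 100))
  keep <- prefilter_genes(m)
  expect_equal(attr(keep, "thresholds"), c(min_counts = 3, min_cells = 1))

  # boundary behaviour at 1300 cells: >= 39 counts in >= 13 cells
  nc <- 1300
  x <- matrix(0, 3, nc)
  x[1, 1:13] <- 3                      # 39 counts in 13 cells: kept
  x[2, 1:13] <- c(rep(3, 12), 2)      # 38 counts in 13 cells: dropped
  x[3, 1:12] <- 4                      # 48 counts in 12 cells: dropped
  m2 <- toy_umi(x)
  keep2 <- prefilter_genes(m2)
  expect_equal(attr(keep2, "thresholds"),
               c(min_counts = 39, min_cells = 13))
  expect_identical(as.character(keep2), "g1")
})

test_that("AUC worked examples match the recovery-curve definition", {
  cnt <- matrix(c(10, 8, 7, 6, 5, 4, 3, 2, 1, 0.5), ncol = 1) * 2
  m <- toy_umi(round(cnt), genes = paste0("g", 1:10))
  # regulon occupying the top ranks is maximal
  expect_equal(unname(auc_score(m, list(R = paste0("g", 1:5)), k = 9)[1, 1]), 1)
  # regulon at ranks 2 and 4 with k = 5: hits (0,1,1,2,2) -> 6/9
  expect_equal(unname(auc_score(m, list(R = c("g2", "g4")), k = 5)[1, 1]), 2 / 3)
  # no regulon gene in the top k
  expect_equal(unname(auc_score(m, list(R = c("g9", "g10")), k = 3)[1, 1]), 0)
  expect_warning(a <- auc_score(m, list(R = "absent"), k = 3), "no genes")
  expect_true(all(is.nan(a)))
  expect_error(auc_score(m, list(R = "g1"), k = 99), "exceeds")
})

test_that("AUC equals brute-force enumeration on random instances", {
  set.seed(41)
  for (i in 1:100) {
    ng <- 20
    counts <- sample(1000, ng)          # distinct: rank order unambiguous
    k <- sample(3:10, 1)
    rsize <- sample(2:6, 1)
    ridx <- sample(ng, rsize)
    m <- toy_umi(matrix(counts, ncol = 1))
    a <- auc_score(m, list(R = paste0("g", ridx)), k = k)[1, 1]
    ref <- auc_bruteforce(counts, ridx, k, order(-counts))
    expect_equal(unname(a), ref, label = sprintf("instance %d", i))
  }
})

test_that("AUC is invariant to monotone transforms of a cell's counts", {
  set.seed(42)
  counts <- sample(500, 30)
  m1 <- toy_umi(matrix(counts, ncol = 1))
  m2 <- toy_umi(matrix(counts * 7L, ncol = 1))
  reg <- list(R = paste0("g", c(2, 9, 17)))
  expect_equal(auc_score(m1, reg, k = 6, seed = 3),
               auc_score(m2, reg, k = 6, seed = 3))
})

test_that("tie-breaking is seeded and reproducible", {
  m <- toy_umi(matrix(c(5, 5, 5, 0, 0, 0), ncol = 1))
  reg <- list(R = c("g1", "g4"))
  a1 <- auc_score(m, reg, k = 3, seed = 9)
  a2 <- auc_score(m, reg, k = 3, seed = 9)
  expect_identical(a1, a2)
})

test_that("binarization applies the distribution-dependent threshold rules", {
  v <- with_seed(51, rnorm(1000, 0.20, 0.05))
  bz <- binarize_regulon(v, n_boot = 300, seed = 1)
  expect_identical(bz$rule, "mean+2sd")
  expect_equal(bz$threshold, mean(v) + 2 * sd(v))
  expect_identical(bz$active, v > bz$threshold)

  mix <- with_seed(52, c(rnorm(500, 0.2, 0.02), rnorm(500, 0.6, 0.02)))
  bz2 <- binarize_regulon(mix, n_boot = 300, seed = 1)
  expect_identical(bz2$rule, "kde-trough")
  expect_gt(bz2$threshold, 0.35)
  expect_lt(bz2$threshold, 0.45)
  expect_gt(bz2$threshold, 0.2)  # strictly between the component means
  expect_lt(bz2$threshold, 0.6)

  const <- rep(0.4, 100)
  bz3 <- binarize_regulon(const)
  expect_identical(bz3$rule, "degenerate")
  expect_equal(bz3$threshold, 0.4)
  expect_false(any(bz3$active))
})

test_that("regulons below 1% activity are dropped; empty matrices warn", {
  set.seed(61)
  n <- 1000
  # active in ~0.5% of cells: clearly bimodal but too rare
  rare <- c(rnorm(n - 5, 0.1, 0.01), rnorm(5, 0.9, 0.01))
  common <- c(rnorm(n - 300, 0.1, 0.01), rnorm(300, 0.9, 0.01))
  auc <- rbind(rare = sample(rare), common = sample(common))
  colnames(auc) <- paste0("c", 1:n)
  class(auc) <- c("auc_matrix", class(auc))
  res <- binarize_matrix(auc, n_boot = 300, seed = 1)
  expect_false(res$report$retained[res$report$regulon == "rare"])
  expect_true(res$report$retained[res$report$regulon == "common"])

  zeros <- matrix(0, 2, 50, dimnames = list(c("r1", "r2"), paste0("c", 1:50)))
  class(zeros) <- c("auc_matrix", class(zeros))
  expect_warning(res0 <- binarize_matrix(zeros), "no regulon")
  expect_equal(nrow(res0$binary), 0)
})

test_that("the simulated ISL1 regulon is bimodal and amnion-specific", {
  proc <- get_small_processed()
  sim <- proc$sim
  tr <- sim$truth
  keep <- prefilter_genes(proc$umi)
  sub <- umi_subset(proc$umi, genes = keep)
  regs <- setNames(list(c(tr$regulon$tf, tr$regulon$targets)), "ISL1_regulon")
  auc <- auc_score(sub, regs, seed = 3)
  res <- binarize_matrix(auc, n_boot = 500, seed = 4)
  rep_row <- res$report[res$report$regulon == "ISL1_regulon", ]
  expect_true(rep_row$retained)
  expect_identical(rep_row$modality, "bimodal")
  act <- res$binary["ISL1_regulon", ]
  truth_am <- tr$cell_type[colnames(res$binary)] %in% c("AM-1", "AM-2")
  sens <- sum(act & truth_am) / sum(truth_am)
  spec <- sum(!act & !truth_am) / sum(!truth_am)
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})
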
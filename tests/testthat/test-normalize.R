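test_that("log-normalization and z-scaling match hand arithmetic", {
  m <- toy_umi(matrix(c(10, 90), 2, 1), genes = c("a", "b"))
  y <- log_normalize_scale(m, scale_total = 10000, scale = FALSE)
  expect_equal(y["a", 1], log(1 + 1000), tolerance = 1e-12)

  # constant normalized values scale to zero rows
  m2 <- toy_umi(rbind(a = c(10, 20), b = c(90, 180), c = c(0, 0)))
  z <- log_normalize_scale(m2)
  expect_equal(unname(z["a", ]), c(0, 0))
  expect_equal(unname(z["c", ]), c(0, 0))
  m3 <- toy_umi(rbind(a = c(1, 0), b = c(1, 0)))
  expect_error(log_normalize_scale(m3), "zero total")
})

test_that("NB dispersion is recovered from simulated counts", {
  set.seed(21)
  ng <- 200; nc <- 2000
  p <- rep(1 / ng, ng)
  N <- round(rlnorm(nc, log(3000), 0.3))
  mu <- outer(p, N)
  x <- matrix(rnbinom(ng * nc, size = 10, mu = mu), ng, nc)
  m <- toy_umi(x)
  fit <- fit_nb_model(m)
  expect_gt(median(fit$theta), 7)
  expect_lt(median(fit$theta), 13)
})

test_that("counts proportional to depth hit the Poisson (upper) bound", {
  N <- c(100, 200, 300, 400, 500, 600)
  x <- rbind(g1 = N * 0.1, g2 = N * 0.9)
  m <- toy_umi(x)
  fit <- fit_nb_model(m)
  expect_equal(unname(fit$theta_raw), c(1e6, 1e6))
})

test_that("identical count vectors get identical dispersions", {
  set.seed(3)
  base <- rnbinom(50, size = 5, mu = 4)
  x <- rbind(g1 = base, g2 = base, g3 = rnbinom(50, size = 5, mu = 6))
  fit <- fit_nb_model(toy_umi(x))
  expect_identical(fit$theta_raw[["g1"]], fit$theta_raw[["g2"]])
  expect_identical(fit$theta[["g1"]], fit$theta[["g2"]])
})

test_that("Pearson residuals follow the NB variance formula and clip", {
  # x = 8, mu = 4, theta = 4 -> z = 4 / sqrt(4 + 4) = sqrt(2)
  fit <- structure(list(
    p = c(g = 0.5), theta_raw = c(g = 4), theta = c(g = 4),
    clip_bound = 10, gene_mean = 4, n_cells = 1
  ), class = "nb_fit")
  m <- toy_umi(matrix(8, 1, 1), genes = "g")  # N_c = 8, p = 0.5 -> mu = 4
  z <- pearson_residuals(m, fit)
  expect_equal(z[1, 1], 4 / sqrt(4 + 4), tolerance = 1e-12)

  # theta -> infinity reduces to the Poisson residual
  fit$theta <- c(g = 1e12)
  z2 <- pearson_residuals(m, fit)
  expect_equal(z2[1, 1], 4 / sqrt(4), tolerance = 1e-4)

  # x = mu gives exactly zero
  m0 <- toy_umi(matrix(4, 1, 1), genes = "g")
  fit0 <- fit; fit0$p <- c(g = 1)
  expect_equal(pearson_residuals(m0, fit0)[1, 1], 0)
})

test_that("no residual exceeds the sqrt(n_cells) clip bound", {
  proc <- get_small_processed()
  expect_lte(max(abs(proc$residuals)), sqrt(n_cells(proc$umi)))
})

test_that("welch_t agrees with the independent t.test oracle", {
  w <- welch_t(c(2.1, 2.5, 1.9, 2.4), c(1.0, 1.2, 0.8, 1.1))
  ref <- t.test(c(2.1, 2.5, 1.9, 2.4), c(1.0, 1.2, 0.8, 1.1))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(w$p, ref$p.value, tolerance = 1e-10)

  set.seed(17)
  for (i in 1:100) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 2))
    w <- welch_t(a, b); ref <- t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }

  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_equal(welch_t(c(1, 1), c(2, 2))$p, .Machine$double.xmin)
})

test_that("row-wise Welch matches the scalar implementation", {
  set.seed(5)
  A <- matrix(rnorm(60), 3); B <- matrix(rnorm(45, 0.5), 3)
  rows <- welch_t_rows(A, B)
  for (g in 1:3) {
    w <- welch_t(A[g, ], B[g, ])
    expect_equal(rows$t[g], w$t, tolerance = 1e-12)
    expect_equal(rows$p[g], w$p, tolerance = 1e-12)
  }
})

test_that("the null band is zero for zero residuals and seeded-deterministic", {
  z <- matrix(0, 50, 40)
  expect_equal(permutation_null_band(z, c(10, 10), 20, seed = 1)$band, 0)
  z2 <- matrix(rnorm(50 * 40), 50, 40)
  b1 <- permutation_null_band(z2, c(10, 10), 20, seed = 4)
  b2 <- permutation_null_band(z2, c(10, 10), 20, seed = 4)
  expect_identical(b1$band, b2$band)
  expect_error(permutation_null_band(z2, c(1, 10), 20), ">= 2")
})

test_that("the pooled band matches normal theory for iid residuals", {
  set.seed(8)
  z <- matrix(rnorm(2000 * 200), 2000, 200)
  b <- permutation_null_band(z, c(100, 100), n_partitions = 100,
                             percentile = 99.9, seed = 3)
  # |N(0, 2/100)| 99.9th percentile = qnorm(0.9995) * sqrt(0.02) ~ 0.465
  ref <- qnorm(1 - 0.001 / 2) * sqrt(2 / 100)
  expect_lt(abs(b$band - ref) / ref, 0.10)
})

test_that("BH adjustment matches hand computation", {
  expect_equal(bh_fdr(0.005), 0.005)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)))
})
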
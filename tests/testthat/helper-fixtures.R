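# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

small_cfg <- function(...) {
  sim_config(n_genes = 700, n_cells_per_condition = 300, ...)
}

small_qc_thresholds <- function() {
  # 700-gene fixtures express fewer genes per cell than full-size data
  qc_thresholds(min_genes_per_cell = 100)
}

get_small_sim <- function() {
  if (is.null(.fixtures$small_sim)) {
    .fixtures$small_sim <- simulate_dataset(small_cfg(), seed = 42)
  }
  .fixtures$small_sim
}

# QCed + ambient-corrected small dataset with residuals and embedding
get_small_processed <- function() {
  if (is.null(.fixtures$small_proc)) {
    sim <- get_small_sim()
    qc <- apply_qc_filters(sim$umi, small_qc_thresholds(),
                           sim$truth$mito_genes)
    epi <- intersect(
      names(sim$truth$cell_type)[sim$truth$cell_type == "Epi"],
      barcodes(qc$umi)
    )
    est <- estimate_ambient_fraction(qc$umi, sim$truth$reporter_genes, epi)
    mqc <- correct_ambient(qc$umi, est)
    fit <- fit_nb_model(mqc, seed = 1)
    z <- pearson_residuals(mqc, fit)
    emb <- pca_knn_embed(z, n_dims = 20, k = 15)
    .fixtures$small_proc <- list(sim = sim, qc = qc, est = est, umi = mqc,
                                 fit = fit, residuals = z, emb = emb)
  }
  .fixtures$small_proc
}

# tiny hand-built count matrix
toy_umi <- function(mat, genes = NULL, cells = NULL, meta = NULL) {
  if (is.null(genes)) genes <- rownames(mat) %||% sprintf("g%d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- colnames(mat) %||% sprintf("c%d", seq_len(ncol(mat)))
  m <- Matrix::Matrix(mat, sparse = TRUE)
  dimnames(m) <- list(genes, cells)
  umi_matrix(m, meta)
}
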
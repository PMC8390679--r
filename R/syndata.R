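#' Cell population names used by the simulator
#' @export
CELL_TYPES <- c("Epi", "AM-1", "AM-2", "meso-1", "meso-2",
                "Endo", "Trophoblast", "ExE-Mech")

AMNION_TYPES <- c("AM-1", "AM-2")
MESO_TYPES <- c("meso-1", "meso-2")
EPI_DERIVED <- c("Epi", "AM-1", "AM-2", "meso-1", "meso-2")

default_proportions <- function() {
  wt <- c("Epi" = 0.35, "AM-1" = 0.10, "AM-2" = 0.10,
          "meso-1" = 0.10, "meso-2" = 0.10,
          "Endo" = 0.10, "Trophoblast" = 0.10, "ExE-Mech" = 0.15)
  mt <- wt
  # Mutant embryos fail to form mesoderm; the cells accumulate in the amnion
  # compartment instead, so the mesoderm weight is moved onto AM-1/AM-2.
  mt[MESO_TYPES] <- 0.01
  mt[AMNION_TYPES] <- mt[AMNION_TYPES] + (0.10 - 0.01)
  list(wt = wt / sum(wt), mt = mt / sum(mt))
}

#' Build a simulation configuration
#'
#' Returns the default configuration of the synthetic embryo-atlas generator,
#' optionally overriding named fields. Defaults encode the study conditions
#' the downstream stages are exercised under: eight populations (epiblast,
#' two amnion, two mesoderm, endoderm, trophoblast, extraembryonic
#' mesenchyme), a wild-type and an ISL1-mutant condition (regulon-target
#' downregulation by `delta` in amnion cells plus mesoderm depletion),
#' trophoblast-exclusive "CG-like" ambient reporter genes mixed into every
#' cell at rate `rho_true`, lognormal library sizes and negative-binomial
#' counts with inverse-dispersion `theta`, and a latent epiblast pseudotime
#' driving naive-down / primed-up gene dynamics.
#'
#' @param ... Named overrides of configuration fields (unknown names error).
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, n_cells_per_condition = 200)
sim_config <- function(...) {
  cfg <- list(
    n_genes = 2000L,
    n_cells_per_condition = 1500L,
    cell_type_proportions = default_proportions(),
    marker_block_size = 25L,
    regulon_tf = "ISL1",
    regulon_n_targets = 50L,
    delta = 0.3,
    rho_true = 0.10,
    n_reporter_genes = 3L,
    reporter_share = 0.20,   # share of trophoblast transcripts per reporter
    n_mito_genes = 13L,
    mito_fraction = 0.03,    # expected mitochondrial share in every type
    libsize_meanlog = log(5000),
    libsize_sdlog = 0.4,
    theta = 10,
    n_naive_genes = 20L,
    n_primed_genes = 20L,
    marker_fold = 8,
    target_fold = 5,         # amnion elevation of regulon targets
    pt_fold = 6,             # pseudotime gene amplitude in epiblast
    day = "D14",
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("overrides must be named")
    }
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  assert_count(cfg$n_genes, "n_genes")
  assert_count(cfg$n_cells_per_condition, "n_cells_per_condition")
  assert_count(cfg$marker_block_size, "marker_block_size")
  assert_count(cfg$regulon_n_targets, "regulon_n_targets")
  assert_count(cfg$n_reporter_genes, "n_reporter_genes")
  assert_count(cfg$n_mito_genes, "n_mito_genes")
  assert_fraction(cfg$delta, "delta", lo = 0, hi = 1, lo_open = TRUE)
  assert_fraction(cfg$rho_true, "rho_true", lo = 0, hi = 1, hi_open = TRUE)
  assert_fraction(cfg$mito_fraction, "mito_fraction", lo = 0, hi = 1, hi_open = TRUE)
  assert_fraction(cfg$reporter_share, "reporter_share", lo = 0, hi = 1 / cfg$n_reporter_genes, hi_open = TRUE)
  props <- cfg$cell_type_proportions
  if (!is.list(props) || !setequal(names(props), c("wt", "mt"))) {
    stop("cell_type_proportions must be a list with elements 'wt' and 'mt'")
  }
  for (cond in c("wt", "mt")) {
    p <- props[[cond]]
    if (!setequal(names(p), CELL_TYPES)) {
      stop("proportions must be named with the eight cell types")
    }
    if (any(p < 0)) stop("proportions must be nonnegative")
    if (abs(sum(p) - 1) > 1e-6) {
      stop(sprintf("proportions for '%s' do not sum to 1 (sum = %.6f)", cond, sum(p)))
    }
    props[[cond]] <- p[CELL_TYPES] / sum(p)
  }
  cfg$cell_type_proportions <- props
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param overrides Named list of overrides (same as `...` of `sim_config`).
#' @export
build_default_config <- function(overrides = list()) {
  do.call(sim_config, overrides)
}

sim_gene_table <- function(cfg) {
  n <- cfg$n_genes
  n_special <- 8L * cfg$marker_block_size + (cfg$regulon_n_targets + 1L) +
    cfg$n_reporter_genes + cfg$n_mito_genes +
    cfg$n_naive_genes + cfg$n_primed_genes
  if (n < n_special + 50L) {
    stop(sprintf("n_genes = %d too small for the structured gene blocks (%d needed)",
                 n, n_special + 50L))
  }
  ids <- sprintf("G%04d", seq_len(n))
  role <- rep("background", n)
  type_of <- rep(NA_character_, n)
  i <- 1L
  take <- function(k) { idx <- i:(i + k - 1L); i <<- i + k; idx }
  for (ct in CELL_TYPES) {
    idx <- take(cfg$marker_block_size)
    ids[idx] <- sprintf("MK-%s-%02d", gsub("[^A-Za-z0-9]", "", ct),
                        seq_along(idx))
    role[idx] <- "marker"
    type_of[idx] <- ct
  }
  idx <- take(1L)
  ids[idx] <- cfg$regulon_tf
  role[idx] <- "regulon_tf"
  idx <- take(cfg$regulon_n_targets)
  ids[idx] <- sprintf("TGT-%03d", seq_along(idx))
  # BMP4- and WNT6-like amnion signalling genes are among the targets and are
  # given high baseline expression (both are highly expressed in amnion).
  ids[idx[1L]] <- "BMP4"
  ids[idx[2L]] <- "WNT6"
  role[idx] <- "regulon_target"
  idx <- take(cfg$n_reporter_genes)
  ids[idx] <- sprintf("CGB%d", seq_along(idx))
  role[idx] <- "reporter"
  idx <- take(cfg$n_mito_genes)
  ids[idx] <- sprintf("MT-%02d", seq_along(idx))
  role[idx] <- "mito"
  idx <- take(cfg$n_naive_genes)
  ids[idx] <- sprintf("NAIVE-%02d", seq_along(idx))
  role[idx] <- "naive"
  idx <- take(cfg$n_primed_genes)
  ids[idx] <- sprintf("PRIMED-%02d", seq_along(idx))
  role[idx] <- "primed"
  data.frame(gene_id = ids, role = role, marker_type = type_of,
             stringsAsFactors = FALSE)
}

# Unnormalized per-type intensity matrix (types x genes). Epiblast pseudotime
# genes are set to their t = 0.5 average here; per-cell profiles replace them.
sim_intensity <- function(cfg, genes, lambda0) {
  n <- cfg$n_genes
  M <- matrix(rep(lambda0, each = length(CELL_TYPES)),
              nrow = length(CELL_TYPES), dimnames = list(CELL_TYPES, genes$gene_id))
  for (ct in CELL_TYPES) {
    idx <- which(genes$role == "marker" & genes$marker_type == ct)
    M[ct, idx] <- M[ct, idx] * cfg$marker_fold
    M[setdiff(CELL_TYPES, ct), idx] <- M[setdiff(CELL_TYPES, ct), idx] * 0.2
  }
  reg <- which(genes$role %in% c("regulon_tf", "regulon_target"))
  M[AMNION_TYPES, reg] <- M[AMNION_TYPES, reg] * cfg$target_fold
  M[setdiff(CELL_TYPES, AMNION_TYPES), reg] <-
    M[setdiff(CELL_TYPES, AMNION_TYPES), reg] * 0.1
  pt <- which(genes$role %in% c("naive", "primed"))
  M["Epi", pt] <- M["Epi", pt] * cfg$pt_fold * 0.5
  M[setdiff(CELL_TYPES, "Epi"), pt] <- M[setdiff(CELL_TYPES, "Epi"), pt] * 0.3
  # Reporters: zero endogenous rate outside trophoblast; inside, each reporter
  # is reporter_share of the trophoblast transcriptome (CG-like dominance).
  rep_idx <- which(genes$role == "reporter")
  M[, rep_idx] <- 0
  s <- cfg$reporter_share * cfg$n_reporter_genes
  troph_rest <- sum(M["Trophoblast", ])
  M["Trophoblast", rep_idx] <- (cfg$reporter_share * troph_rest / (1 - s))
  # Mitochondrial genes: scaled so their combined share is mito_fraction.
  mito_idx <- which(genes$role == "mito")
  for (ct in CELL_TYPES) {
    rest <- sum(M[ct, -mito_idx])
    M[ct, mito_idx] <- rest * cfg$mito_fraction / (1 - cfg$mito_fraction) /
      length(mito_idx)
  }
  M
}

#' Simulate a two-condition embryo scRNA-seq dataset with known truth
#'
#' Draws a wild-type and an ISL1-mutant dataset under the configured study
#' conditions. Endogenous counts follow NB(mean = libsize x type profile x
#' effect, inverse-dispersion `theta`); ambient contamination is mixed in at
#' the rate level as `(1 - rho) * endogenous + rho * ambient`, where the
#' ambient profile is the library-size-weighted aggregate endogenous profile
#' of the condition's cells (so reporter genes, endogenously exclusive to
#' trophoblast, appear at low level everywhere). Identical `(config, seed)`
#' give identical output.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with elements `umi` (a [umi_matrix] whose `cell_meta` has
#'   `condition`, `day`, `batch`) and `truth` (a `sim_truth` list: per-cell
#'   `cell_type`, `condition`, latent `pseudotime` for epiblast cells, the
#'   regulon membership, per-gene applied `effect` (1 or delta), `rho_true`,
#'   the per-condition `ambient_profile`, expected endogenous mean profiles
#'   `mu_tilde`, and the gene annotation table).
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  cfg <- validate_sim_config(config)
  with_seed(seed, {
    genes <- sim_gene_table(cfg)
    lambda0 <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
    # BMP4/WNT6: strongly expressed amnion signalling genes.
    hi <- quantile(lambda0, 0.99)
    lambda0[match(c("BMP4", "WNT6"), genes$gene_id)] <- hi * c(3, 2.5)
    M <- sim_intensity(cfg, genes, lambda0)
    prof <- M / rowSums(M)  # per-type normalized endogenous profiles

    pt_idx <- which(genes$role %in% c("naive", "primed"))
    naive_idx <- which(genes$role == "naive")
    primed_idx <- which(genes$role == "primed")
    reg_idx <- which(genes$role %in% c("regulon_tf", "regulon_target"))

    conds <- c("wt", "mt")
    mats <- list(); metas <- list(); truths <- list()
    ambient <- matrix(0, cfg$n_genes, 2, dimnames = list(genes$gene_id, conds))
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      nc <- cfg$n_cells_per_condition
      ncounts <- as.vector(rmultinom(1, nc, cfg$cell_type_proportions[[cond]]))
      cell_type <- rep(CELL_TYPES, ncounts)
      libsize <- rlnorm(nc, cfg$libsize_meanlog, cfg$libsize_sdlog)
      t_latent <- rep(NA_real_, nc)
      is_epi <- cell_type == "Epi"
      t_latent[is_epi] <- runif(sum(is_epi))

      # per-cell endogenous rate matrix (genes x cells)
      R <- t(prof[cell_type, , drop = FALSE])
      if (any(is_epi)) {
        # replace pseudotime-gene entries and renormalize epiblast cells
        Mepi <- M["Epi", ]
        amp <- Mepi[pt_idx] / 0.5  # intensity at full amplitude
        for (j in which(is_epi)) {
          v <- Mepi
          v[naive_idx] <- amp[match(naive_idx, pt_idx)] * (1 - t_latent[j])
          v[primed_idx] <- amp[match(primed_idx, pt_idx)] * t_latent[j]
          R[, j] <- v / sum(v)
        }
      }
      if (cond == "mt") {
        in_am <- cell_type %in% AMNION_TYPES
        R[reg_idx, in_am] <- R[reg_idx, in_am] * cfg$delta
      }
      # ambient profile: library-size-weighted aggregate endogenous rates
      b <- as.vector(R %*% libsize)
      b <- b / sum(b)
      ambient[, ci] <- b
      rate <- (1 - cfg$rho_true) * R + cfg$rho_true * b
      mu_mat <- sweep(rate, 2, libsize, "*")
      x <- rnbinom(length(mu_mat), size = cfg$theta, mu = as.vector(mu_mat))
      X <- Matrix::Matrix(matrix(x, nrow = cfg$n_genes), sparse = TRUE)
      bc <- sprintf("%s-%04d", toupper(cond), seq_len(nc))
      dimnames(X) <- list(genes$gene_id, bc)
      mats[[cond]] <- X
      metas[[cond]] <- data.frame(
        row.names = bc, condition = rep(cond, nc), day = rep(cfg$day, nc),
        batch = rep("B1", nc), stringsAsFactors = FALSE
      )
      truths[[cond]] <- data.frame(
        row.names = bc, barcode = bc, condition = rep(cond, nc),
        cell_type = cell_type,
        pseudotime = t_latent, stringsAsFactors = FALSE
      )
    }
    counts <- cbind(mats$wt, mats$mt)
    meta <- rbind(metas$wt, metas$mt)
    cells <- rbind(truths$wt, truths$mt)

    # expected endogenous type x gene mean profiles (wild type; mutant amnion
    # rows additionally recorded with the delta effect applied)
    prof_named <- prof
    mu_tilde_out <- list(
      wt = prof_named,
      mt = {
        p <- prof_named
        p[AMNION_TYPES, reg_idx] <- p[AMNION_TYPES, reg_idx] * cfg$delta
        p
      }
    )

    truth <- structure(list(
      cells = cells,
      cell_type = setNames(cells$cell_type, cells$barcode),
      condition = setNames(cells$condition, cells$barcode),
      pseudotime = setNames(cells$pseudotime, cells$barcode),
      regulon = list(tf = cfg$regulon_tf,
                     targets = genes$gene_id[genes$role == "regulon_target"]),
      gene_effect = setNames(
        ifelse(genes$role %in% c("regulon_tf", "regulon_target"),
               cfg$delta, 1),
        genes$gene_id
      ),
      rho_true = cfg$rho_true,
      ambient_profile = ambient,
      mu_tilde = mu_tilde_out,
      genes = genes,
      marker_sets = split(genes$gene_id[genes$role == "marker"],
                          genes$marker_type[genes$role == "marker"])[CELL_TYPES],
      reporter_genes = genes$gene_id[genes$role == "reporter"],
      mito_genes = genes$gene_id[genes$role == "mito"],
      naive_genes = genes$gene_id[genes$role == "naive"],
      primed_genes = genes$gene_id[genes$role == "primed"]
    ), class = "sim_truth")
    list(umi = umi_matrix(counts, meta), truth = truth)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the 10x-style triplet, `metadata.csv`, `truth.json`, and GMT files
#' for the true regulon, the per-type marker sets, and the naive/primed
#' pluripotency signatures.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tenx_triplet(sim$umi, dir)
  meta <- cbind(barcode = rownames(sim$umi$cell_meta), sim$umi$cell_meta)
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(
      cells = tr$cells, rho_true = tr$rho_true,
      regulon = tr$regulon, genes = tr$genes,
      ambient_profile = as.data.frame(tr$ambient_profile)
    ),
    file.path(dir, "truth.json"), dataframe = "columns", auto_unbox = TRUE,
    digits = NA
  )
  write_gmt(c(
    setNames(list(c(tr$regulon$tf, tr$regulon$targets)),
             paste0(tr$regulon$tf, "_regulon"))
  ), file.path(dir, "regulons.gmt"))
  write_gmt(tr$marker_sets, file.path(dir, "markers.gmt"))
  write_gmt(list(naive = tr$naive_genes, primed = tr$primed_genes),
            file.path(dir, "signatures.gmt"))
  invisible(dir)
}
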
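#' Pipeline configuration
#'
#' One object holding every stage's parameters plus the global seed. In
#' `"simulate"` mode the input is drawn from [simulate_dataset()]; in
#' `"load"` mode a 10x triplet plus `metadata.csv` and the marker / regulon /
#' signature GMT files are read from `input_dir`.
#'
#' @param input_mode `"simulate"` or `"load"`.
#' @param input_dir Directory with the triplet and GMT files (load mode).
#' @param out_dir Optional output directory for the CSV/JSON bundle.
#' @param seed Global seed; every stage derives a named substream from it.
#' @param sim A [sim_config()].
#' @param qc A [qc_thresholds()].
#' @param de A [de_config()].
#' @param n_dims,k PCA dimensions and kNN neighbours.
#' @param resolution Clustering resolution.
#' @param top_n Pseudotime genes to keep after Moran ranking.
#' @param alpha,min_active_frac,n_boot Regulon binarization parameters.
#' @param stages Character vector of stages to run (in pipeline order);
#'   `"all"` keeps everything.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_mode = c("simulate", "load"),
                            input_dir = NULL, out_dir = NULL, seed = 1,
                            sim = sim_config(), qc = qc_thresholds(),
                            de = de_config(), n_dims = 30, k = 15,
                            resolution = 1.0, top_n = 100, alpha = 0.05,
                            min_active_frac = 0.01, n_boot = 1000,
                            stages = "all") {
  input_mode <- match.arg(input_mode)
  if (input_mode == "load" && is.null(input_dir)) {
    stop("load mode requires input_dir")
  }
  structure(list(
    input_mode = input_mode, input_dir = input_dir, out_dir = out_dir,
    seed = seed, sim = sim, qc = qc, de = de, n_dims = n_dims, k = k,
    resolution = resolution, top_n = top_n, alpha = alpha,
    min_active_frac = min_active_frac, n_boot = n_boot, stages = stages
  ), class = "pipeline_config")
}

pipeline_inputs <- function(config) {
  if (config$input_mode == "simulate") {
    sim <- simulate_dataset(config$sim, seed = derive_seed(config$seed, "simulate"))
    tr <- sim$truth
    list(
      umi = sim$umi, truth = tr,
      marker_sets = tr$marker_sets,
      regulons = setNames(list(c(tr$regulon$tf, tr$regulon$targets)),
                          paste0(tr$regulon$tf, "_regulon")),
      signatures = list(naive = tr$naive_genes, primed = tr$primed_genes),
      reporter_genes = tr$reporter_genes,
      mito_genes = tr$mito_genes
    )
  } else {
    dir <- config$input_dir
    if (!dir.exists(dir)) stop("[input] input directory not found: ", dir)
    umi <- read_tenx_triplet(dir)
    gmt_or_null <- function(f) {
      p <- file.path(dir, f)
      if (file.exists(p)) read_gmt(p) else NULL
    }
    list(
      umi = umi, truth = NULL,
      marker_sets = gmt_or_null("markers.gmt"),
      regulons = gmt_or_null("regulons.gmt"),
      signatures = gmt_or_null("signatures.gmt"),
      reporter_genes = grep("^CG", gene_ids(umi), value = TRUE),
      mito_genes = grep("^MT-", gene_ids(umi), value = TRUE)
    )
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, QC and ambient correction, NB normalization,
#' embedding + clustering + marker annotation, condition-wise composition,
#' signature scoring, epiblast pseudotime with Moran ranking, regulon AUC
#' binarization, and amnion mutant-vs-wild-type differential expression.
#' Identical config + seed give an identical report. The report carries
#' three headline booleans: mesoderm depletion in the mutant, significant
#' BMP4 downregulation in mutant amnion, and an amnion-specific active ISL1
#' regulon.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list of per-stage summaries and tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- sprintf(...)
    message(sprintf("[%s] %s", stage, log[[stage]]))
  }
  stage_err <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  inp <- stage_err("input", pipeline_inputs(config))
  umi <- inp$umi
  note("input", "%d genes x %d cells", n_genes(umi), n_cells(umi))

  # --- QC ---------------------------------------------------------------
  qc <- stage_err("qc", apply_qc_filters(umi, config$qc, inp$mito_genes))
  note("qc", "%d/%d cells and %d/%d genes retained",
       n_cells(qc$umi), n_cells(umi), n_genes(qc$umi), n_genes(umi))

  # --- ambient estimation / correction ---------------------------------
  # reporter population: cells whose top marker signature is the epiblast
  # one (the POU5F1-positive population, which cannot express CG genes)
  amb <- stage_err("ambient", {
    S <- score_signatures(qc$umi, inp$marker_sets)
    top <- rownames(S)[apply(S, 2, which.max)]
    epi_cells <- barcodes(qc$umi)[top == "Epi"]
    est <- estimate_ambient_fraction(
      qc$umi, intersect(inp$reporter_genes, gene_ids(qc$umi)), epi_cells
    )
    list(est = est, corrected = correct_ambient(qc$umi, est))
  })
  note("ambient", "rho_hat = %.4f over %d reporter cells",
       amb$est$rho, length(amb$est$reporter_population))
  mqc <- amb$corrected

  # --- normalization ----------------------------------------------------
  fit <- stage_err("normalize", fit_nb_model(
    mqc, max_cells_fit = config$de$max_cells_fit,
    seed = derive_seed(config$seed, "fit")
  ))
  z <- pearson_residuals(mqc, fit)
  note("normalize", "residuals clipped at %.2f", fit$clip_bound)

  # --- embedding / clustering / annotation ------------------------------
  emb <- stage_err("cluster", pca_knn_embed(
    z, n_dims = min(config$n_dims, n_cells(mqc) - 1), k = config$k
  ))
  assign <- cluster_graph(emb, resolution = config$resolution,
                          seed = derive_seed(config$seed, "cluster"))
  ann <- annotate_clusters(mqc, assign, inp$marker_sets)
  cell_type <- setNames(unname(ann[as.character(assign$labels)]),
                        names(assign$labels))
  note("cluster", "%d clusters -> types: %s", nlevels(assign$labels),
       paste(unique(ann), collapse = ", "))
  cond <- setNames(mqc$cell_meta$condition, barcodes(mqc))
  composition <- composition_by_condition(cell_type, cond)

  # --- signatures -------------------------------------------------------
  sig_scores <- stage_err("signatures",
                          score_signatures(mqc, inp$signatures))

  # --- pseudotime (epiblast) -------------------------------------------
  ptime <- stage_err("pseudotime", {
    epi <- barcodes(mqc)[cell_type[barcodes(mqc)] == "Epi"]
    if (length(epi) < config$n_dims + 2) stop("too few epiblast cells")
    sub <- umi_subset(mqc, cells = epi)
    emb_epi <- pca_knn_embed(z[, epi, drop = FALSE],
                             n_dims = min(15, length(epi) - 1), k = config$k)
    root <- select_root(sub, inp$signatures$naive)
    pt <- graph_pseudotime(emb_epi, root)
    dyn <- rank_and_cluster_dynamics(sub, pt, emb_epi, top_n = config$top_n)
    list(pt = pt, dynamics = dyn, cells = epi)
  })
  note("pseudotime", "root %s; %d genes ranked", ptime$pt$root,
       sum(is.finite(ptime$dynamics$moran$I)))

  # --- regulons ---------------------------------------------------------
  reg <- stage_err("regulons", {
    keep <- prefilter_genes(mqc)
    sub <- umi_subset(mqc, genes = keep)
    auc <- auc_score(sub, inp$regulons,
                     seed = derive_seed(config$seed, "tiebreak"))
    bin <- binarize_matrix(auc, alpha = config$alpha,
                           min_active_frac = config$min_active_frac,
                           n_boot = config$n_boot,
                           seed = derive_seed(config$seed, "dip"))
    list(auc = auc, bin = bin, prefilter = attr(keep, "thresholds"))
  })
  note("regulons", "%d/%d regulons retained",
       sum(reg$bin$report$retained), nrow(reg$bin$report))

  # --- differential expression (amnion, mt vs wt) -----------------------
  de <- stage_err("de", {
    am <- barcodes(mqc)[cell_type[barcodes(mqc)] %in% AMNION_TYPES]
    a <- am[cond[am] == "wt"]; b <- am[cond[am] == "mt"]
    if (length(a) < 2 || length(b) < 2) stop("too few amnion cells per condition")
    cfg <- config$de; cfg$seed <- derive_seed(config$seed, "de")
    run_de(mqc, a, b, cfg)   # mean_diff > 0 = down in mutant
  })
  note("de", "%d significant genes", sum(de$significant))

  # --- headline booleans ------------------------------------------------
  frac_of <- function(cc, types) {
    idx <- composition$condition == cc & composition$label %in% types
    sum(composition$fraction[idx])
  }
  n_cond <- table(cond)
  meso_wt <- frac_of("wt", MESO_TYPES); meso_mt <- frac_of("mt", MESO_TYPES)
  se_meso <- sqrt(meso_wt * (1 - meso_wt) / n_cond[["wt"]] +
                    meso_mt * (1 - meso_mt) / n_cond[["mt"]])
  am_wt <- frac_of("wt", AMNION_TYPES); am_mt <- frac_of("mt", AMNION_TYPES)
  se_am <- sqrt(am_wt * (1 - am_wt) / n_cond[["wt"]] +
                  am_mt * (1 - am_mt) / n_cond[["mt"]])
  bmp4 <- de[de$gene == "BMP4", ]
  isl1_row <- grep("ISL1", reg$bin$report$regulon)
  isl1_ok <- FALSE; isl1_purity <- NA_real_
  if (length(isl1_row) == 1 && reg$bin$report$retained[isl1_row] &&
      identical(reg$bin$report$modality[isl1_row], "bimodal")) {
    act <- reg$bin$binary[reg$bin$report$regulon[isl1_row], ]
    isl1_purity <- mean(cell_type[names(act)[act]] %in% AMNION_TYPES)
    isl1_ok <- isl1_purity >= 0.9
  }
  headline <- list(
    mesoderm_depleted_in_mutant =
      unname(meso_mt < meso_wt && (meso_wt - meso_mt) > 3 * se_meso),
    amnion_overrepresented_in_mutant =
      unname(am_mt > am_wt && (am_mt - am_wt) > 3 * se_am),
    bmp4_down_in_mutant_amnion =
      nrow(bmp4) == 1 && bmp4$significant && bmp4$mean_diff > 0,
    isl1_regulon_amnion_specific = unname(isl1_ok)
  )

  report <- structure(list(
    config = config,
    log = log,
    qc = list(n_cells = n_cells(qc$umi), n_genes = n_genes(qc$umi),
              table = qc$qc_table),
    ambient = list(rho = amb$est$rho,
                   n_reporter_cells = length(amb$est$reporter_population)),
    clusters = list(labels = assign$labels, annotation = ann,
                    cell_type = cell_type),
    composition = composition,
    signature_scores = sig_scores,
    pseudotime = ptime,
    regulons = list(report = reg$bin$report, binary = reg$bin$binary,
                    auc = reg$auc, prefilter = reg$prefilter),
    de = de,
    composition_fractions = list(meso_wt = meso_wt, meso_mt = meso_mt,
                                 amnion_wt = am_wt, amnion_mt = am_mt),
    isl1_active_amnion_purity = isl1_purity,
    headline = headline,
    seed = config$seed
  ), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

#' Write a pipeline report bundle
#'
#' CSV tables plus a machine-readable `report.json` of the summaries.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$qc$table, file.path(dir, "qc_table.csv"), row.names = FALSE)
  write.csv(report$composition, file.path(dir, "composition.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$de), file.path(dir, "de_table.csv"),
            row.names = FALSE)
  write.csv(report$regulons$report, file.path(dir, "regulon_binarization.csv"),
            row.names = FALSE)
  write.csv(data.frame(barcode = names(report$clusters$labels),
                       cluster = as.character(report$clusters$labels),
                       cell_type = report$clusters$cell_type[
                         names(report$clusters$labels)]),
            file.path(dir, "clusters.csv"), row.names = FALSE)
  mor <- report$pseudotime$dynamics$moran
  write.csv(mor, file.path(dir, "moran.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    seed = report$seed,
    log = report$log,
    qc = report$qc[c("n_cells", "n_genes")],
    ambient = report$ambient,
    composition_fractions = report$composition_fractions,
    isl1_active_amnion_purity = report$isl1_active_amnion_purity,
    headline = report$headline
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (s in names(x$log)) cat(sprintf("  %-10s %s\n", s, x$log[[s]]))
  cat("headline:\n")
  for (h in names(x$headline)) {
    cat(sprintf("  %-36s %s\n", h, x$headline[[h]]))
  }
  invisible(x)
}
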
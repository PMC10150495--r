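#' Default pipeline configuration
#'
#' Per-stage parameter blocks with the package defaults: spot filter at
#' 200 detected genes, gene filter at 50 counts, resolution grid
#' 0.1-1.2 step 0.05 with reference resolution 0.8, 50 PCs / 50
#' neighbours, log-cpm filter thresholds 2/2/3/3 by compartment, logFC
#' threshold 0.15, and ncenters 3 for reference aggregation.
#'
#' @param seed Global seed; per-stage seeds are derived from it by a
#'   fixed offset so adding a stage never perturbs earlier draws.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(n_control = 2, n_treated = 2),
    filter = list(min_genes = 200, min_gene_count = 50),
    classify = list(cutoffs = NULL),       # NULL = suggest from the data
    hetscan = list(lo = 0.1, hi = 1.2, step = 0.05, ref_resolution = 0.8,
                   n_pcs = 50, k = 50, L = 10, k_neigh = 20),
    de = list(compartment = "human", min_logcpm = NULL,
              logfc_threshold = 0.15, alpha = 0.05),
    interface = list(target = "Astrocyte_Bergmann_glia",
                     comparison = "mouse_rest", radius = 1)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  known <- names(default_pipeline_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  merge_config(default_pipeline_config(), config)
}

#' Run the full synthetic-section analysis pipeline
#'
#' Orchestrates simulate -> spot/gene filter -> species classification ->
#' heterogeneity scan -> per-spot gene-set enrichment -> pseudobulk DE ->
#' interface enrichment on seeded synthetic sections, writing headered
#' CSV/JSON stage outputs plus a manifest (package version, seed, config)
#' into a run directory. Re-running with the same config and seed
#' reproduces the outputs.
#'
#' @param config Configuration list or path to a YAML/JSON file; merged
#'   over [default_pipeline_config()]. Unknown keys are rejected.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("xenohet_run_")) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed

  # stage 1: simulate sections (per-sample seeds derived from the global)
  sims <- list(); conditions <- character(0)
  n_total <- cfg$simulate$n_control + cfg$simulate$n_treated
  for (i in seq_len(n_total)) {
    treated <- i > cfg$simulate$n_control
    sims[[i]] <- simulate_section(simulation_config(
      treatment = treated, seed = seed + i))
    conditions[i] <- if (treated) "treated" else "control"
  }

  # stage 2: QC filters
  ds_list <- lapply(sims, function(s)
    filter_genes_min_count(filter_low_quality_spots(
      s$dataset, cfg$filter$min_genes), cfg$filter$min_gene_count))

  # stage 3: species classification (per-sample cutoffs)
  calls <- list()
  for (i in seq_along(ds_list)) {
    sc <- species_scores(ds_list[[i]])
    cuts <- cfg$classify$cutoffs
    if (is.null(cuts))
      cuts <- suggest_cutoffs(sc$h_scores, sc$m_scores)$cutoffs
    calls[[i]] <- classify_spots(sc$h_scores, sc$m_scores, cuts)
    utils::write.csv(as.data.frame(calls[[i]]),
                     file.path(out_dir, sprintf("labels_%s.csv",
                                                ds_list[[i]]$sample_id)),
                     row.names = FALSE)
  }

  # stage 4: heterogeneity scan on the human spots of each sample
  scans <- list()
  for (i in seq_along(ds_list)) {
    ds <- ds_list[[i]]; call <- calls[[i]]
    hum <- which(call$label == "human")
    norm <- normalise_counts(ds[hum, ], "logcpm")
    k_use <- min(cfg$hetscan$k, length(hum) - 1)
    emb <- build_embedding_graph(norm, n_pcs = cfg$hetscan$n_pcs, k = k_use)
    scans[[i]] <- resolution_scan(
      emb, resolution_grid(cfg$hetscan$lo, cfg$hetscan$hi, cfg$hetscan$step),
      seed = seed, ref_resolution = cfg$hetscan$ref_resolution,
      coords = ds$array_coords[hum, ], L = cfg$hetscan$L,
      k_neigh = cfg$hetscan$k_neigh)
  }
  scan_summary <- data.frame(
    sample = vapply(ds_list, function(d) d$sample_id, ""),
    condition = conditions,
    ci_total = vapply(scans, function(s) s$ci_total, 0),
    mean_shannon = vapply(scans, function(s) mean(s$metrics$shannon), 0),
    mean_simpson = vapply(scans, function(s) mean(s$metrics$simpson), 0))
  jsonlite::write_json(scan_summary, file.path(out_dir, "scan.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  # stage 5: per-spot programme enrichment (PAGE) per sample
  prog_sets <- split(sims[[1]]$truth$genes$gene_id[
    !is.na(sims[[1]]$truth$genes$programme)],
    sims[[1]]$truth$genes$programme[!is.na(sims[[1]]$truth$genes$programme)])
  maps <- list()
  for (i in seq_along(ds_list)) {
    norm <- normalise_counts(ds_list[[i]], "logcpm")
    colnames(norm) <- ds_list[[i]]$genes$gene_id
    maps[[i]] <- page_scores(spot_fold_changes(norm), prog_sets)
    utils::write.csv(
      data.frame(barcode = ds_list[[i]]$barcodes, maps[[i]]$scores),
      file.path(out_dir, sprintf("enrichment_%s.csv",
                                 ds_list[[i]]$sample_id)),
      row.names = FALSE)
  }

  # stage 6: pseudobulk DE (treated vs control)
  pb <- pseudobulk(ds_list, calls, cfg$de$compartment, conditions)
  pb <- filter_low_expression(pb, cfg$de$min_logcpm)
  de <- moderated_de(pb, logfc_threshold = cfg$de$logfc_threshold,
                     alpha = cfg$de$alpha)
  utils::write.csv(de, file.path(out_dir, "de.csv"), row.names = FALSE)

  # stage 7: interface enrichment on ground-truth cell types, sample 1
  truth1 <- sims[[1]]$truth$spots
  keep_bc <- ds_list[[1]]$barcodes
  labels1 <- setNames(truth1$cell_type, truth1$barcode)[keep_bc]
  fis <- interface_enrichment(calls[[1]], ds_list[[1]]$array_coords,
                              labels1, cfg$interface$target,
                              comparison = cfg$interface$comparison,
                              radius = cfg$interface$radius)
  jsonlite::write_json(list(a = fis$a, b = fis$b, c = fis$c, d = fis$d,
                            odds_ratio = fis$odds_ratio, p = fis$p),
                       file.path(out_dir, "fisher.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(package = "xenohet",
                   version = as.character(utils::packageVersion("xenohet")),
                   seed = seed,
                   config = cfg[setdiff(names(cfg), "classify")],
                   samples = vapply(ds_list, function(d) d$sample_id, ""))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(datasets = ds_list, calls = calls, scans = scans,
                 enrichment = maps, de = de, fisher = fis,
                 out_dir = out_dir, config = cfg))
}
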
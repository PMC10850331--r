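#' Default pipeline configuration
#'
#' Returns the full configuration of the workflow as a named list. All
#' randomness derives from `seed`: per-stage seeds are fixed offsets of the
#' root seed so a single knob reproduces the whole run.
#'
#' @param counts,metadata,gmt Optional input paths (counts TSV, metadata
#'   TSV, GMT collection). When `counts` is NULL the synthetic "paper"
#'   preset is simulated.
#' @param outdir Output directory.
#' @param seed Root seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL, gmt = NULL,
                            outdir = tempfile("somscape_run_"), seed = 1L) {
  structure(list(
    paths = list(counts = counts, metadata = metadata, gmt = gmt,
                 outdir = outdir),
    simulate = list(preset = "paper", n_genes = 5000L),
    preprocess = list(min_count = 10, prior_count = 3),
    som = list(grid_side = 40L, epochs = 3L),
    segment = list(k = 20L, min_peak_abs_logfc = 1.0, top_k = 10L,
                   onset_day = 7),
    biclust = list(n_clusters = 5L, cluster_cols = TRUE),
    seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (section in names(raw)) {
    if (section == "seed") { cfg$seed <- as.integer(raw$seed); next }
    if (!section %in% names(cfg))
      stop("unknown config section: ", section)
    for (key in names(raw[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop("unknown config key: ", section, ".", key)
      cfg[[section]][[key]] <- raw[[section]][[key]]
    }
  }
  cfg
}

#' Run the complete workflow
#'
#' preprocess -> hierarchical clustering (9 variants + PCA) -> SOM ->
#' grid segmentation, gene selection, hierarchy reconstruction and
#' efficiency markers -> (optional) over-representation -> bi-clustering.
#' When no counts path is configured the synthetic "paper"-design dataset
#' is simulated first and its ground truth written alongside.
#'
#' All stage outputs are written under `outdir` and a machine-readable
#' `summary.json` records the headline quantities: selected variant,
#' cluster counts, marker list, reconstruction ARI.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all stage results plus `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[somscape] ", ...)
  t0 <- Sys.time()

  # --- inputs ---------------------------------------------------------
  truth <- NULL
  if (is.null(config$paths$counts)) {
    say("simulating synthetic dataset (preset ", config$simulate$preset,
        ", seed ", config$seed, ")")
    sim <- simulate_dataset(config$simulate$preset,
                            n_genes = config$simulate$n_genes,
                            seed = config$seed)
    counts <- sim$counts; metadata <- sim$metadata; truth <- sim$truth
    write_simulation(sim, outdir)
    write_truth(truth, file.path(outdir, "truth.json"))
  } else {
    counts <- read_count_matrix(config$paths$counts)
    metadata <- utils::read.table(config$paths$metadata, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("sample_id", "protocol", "day") %in% names(metadata)))
      stop("metadata must carry sample_id, protocol and day columns")
    if (!"condition" %in% names(metadata))
      metadata$condition <- paste0(metadata$protocol, "_", metadata$day)
  }

  # --- preprocess -----------------------------------------------------
  say("preprocessing ", nrow(counts), " genes x ", ncol(counts), " samples")
  pp <- preprocess_counts(counts, metadata,
                          min_count = config$preprocess$min_count,
                          prior_count = config$preprocess$prior_count)
  utils::write.table(
    data.frame(gene_id = rownames(pp$expr), pp$expr, check.names = FALSE),
    file.path(outdir, "expr_logfc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(tmm_factors = as.list(pp$norm$tmm_factors),
         reference_sample = pp$norm$reference_sample,
         kept_genes = length(pp$kept_genes)),
    file.path(outdir, "normalization.json"), auto_unbox = TRUE, digits = NA)

  # --- hierarchical clustering + PCA ---------------------------------
  say("hierarchical clustering, 9 variants on condition means")
  hc <- run_all_variants(t(pp$expr_mean))
  utils::write.table(hc$variants, file.path(outdir, "hc_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(hc$trees)) {
    v <- hc$variants[i, ]
    tree_to_newick(hc$trees[[i]],
                   file.path(outdir, sprintf("tree_%s_%s.nwk",
                                             v$metric, v$linkage)))
  }
  pca <- pca_scores(pp$expr)

  # --- SOM ------------------------------------------------------------
  say("training ", config$som$grid_side, "x", config$som$grid_side,
      " SOM, ", config$som$epochs, " epochs")
  som_cfg <- som_config(grid_side = config$som$grid_side,
                        epochs = config$som$epochs,
                        seed = config$seed + 1L)
  model <- train_som(pp$expr, som_cfg)
  grid <- metagene_grid(model, pp$expr)
  utils::write.table(gene_positions(model),
                     file.path(outdir, "gene_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- segmentation, selection, markers -------------------------------
  say("segmenting the grid into ", config$segment$k, " clusters")
  seg <- kmeans_grid(grid, k = config$segment$k, seed = config$seed + 2L)
  seg <- significance_filter(seg, config$segment$min_peak_abs_logfc)
  write_segmentation(seg, file.path(outdir, "segmentation.tsv"))
  selected_genes <- select_genes(model, seg)
  sel_variant <- if (!is.na(hc$selected)) hc$variants[hc$selected, ]
                 else data.frame(metric = "euclidean", linkage = "complete")
  recon <- reconstruct_hierarchy(pp$expr_mean,
                                 pp$expr_mean[selected_genes, , drop = FALSE],
                                 metric = sel_variant$metric,
                                 linkage = sel_variant$linkage)
  markers <- NULL
  if ("efficiency" %in% names(metadata) &&
      any(!is.na(metadata$efficiency)) &&
      stats::sd(metadata$efficiency, na.rm = TRUE) > 0) {
    markers <- efficiency_markers(pp$expr, model, seg, metadata,
                                  top_k = config$segment$top_k,
                                  onset_day = config$segment$onset_day)
    jsonlite::write_json(
      list(cluster = markers$cluster,
           efficiency_correlation = markers$cluster_efficiency_cor,
           top_genes = markers$top_genes),
      file.path(outdir, "markers.json"), auto_unbox = TRUE, digits = NA)
  }

  # --- enrichment (optional) -----------------------------------------
  enrichment <- NULL
  if (!is.null(config$paths$gmt)) {
    say("over-representation analysis")
    collection <- read_gmt(config$paths$gmt)
    enrichment <- overrepresentation(selected_genes, collection,
                                     universe = pp$kept_genes)
    utils::write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- bi-clustering on the selected genes ---------------------------
  say("bi-clustering ", length(selected_genes), " selected genes")
  bc <- bicluster(pp$expr_mean[selected_genes, , drop = FALSE],
                  cluster_cols = config$biclust$cluster_cols)
  row_labels <- cut_rows(bc, config$biclust$n_clusters)
  write_bicluster(bc, file.path(outdir, "bicluster_matrix.tsv"))

  summary <- list(
    n_samples = ncol(pp$expr),
    n_genes_kept = length(pp$kept_genes),
    n_hc_variants = nrow(hc$variants),
    selected_variant = if (!is.na(hc$selected))
      paste(sel_variant$metric, sel_variant$linkage, sep = "/") else NA,
    selected_k = if (!is.na(hc$selected)) sel_variant$k else NA,
    n_grid_clusters = seg$k,
    n_significant_clusters = sum(seg$significant),
    n_selected_genes = length(selected_genes),
    reconstruction_ari = recon$ari,
    cophenetic_cor = recon$cophenetic_cor,
    marker_cluster = if (!is.null(markers)) markers$cluster else NA,
    top_markers = if (!is.null(markers)) markers$top_genes else character(),
    seed = config$seed,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(summary[names(summary) != "elapsed_sec"],
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say(sprintf("done in %.1f s; outputs in %s", summary$elapsed_sec, outdir))
  invisible(list(preprocess = pp, hc = hc, pca = pca, model = model,
                 grid = grid, segmentation = seg,
                 selected_genes = selected_genes,
                 reconstruction = recon, markers = markers,
                 enrichment = enrichment, bicluster = bc,
                 row_labels = row_labels, truth = truth,
                 metadata = metadata, summary = summary))
}
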
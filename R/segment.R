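#' K-means segmentation of the metagene grid
#'
#' Partitions the occupied nodes' metagene profiles into `k` clusters by
#' standard Euclidean K-means (k-means++ seeding, `restarts` restarts, best
#' within-cluster sum of squares kept; Lloyd iterations via
#' [stats::kmeans()]). Clusters are labelled `A`, `B`, ... in order of
#' decreasing size. Spatial contiguity on the grid is emergent, not
#' enforced.
#'
#' @param grid A `metagene_grid`.
#' @param k Number of clusters (default 20, labels A-T).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (default 10).
#' @param occupied_only Cluster only nodes with at least one gene (default
#'   TRUE); empty nodes then carry no label.
#' @return A `grid_segmentation`: `labels` (node -> cluster letter, NA for
#'   unclustered nodes), `k`, `profiles` (cluster x sample mean metagene),
#'   `significant` (all TRUE until [significance_filter()]), `inertia`,
#'   `coords`, `sample_ids`, `occupancy`.
#' @export
kmeans_grid <- function(grid, k = 20L, seed = 1L, restarts = 10L,
                        occupied_only = TRUE) {
  stopifnot(inherits(grid, "metagene_grid"))
  if (k < 2L) stop("'k' must be at least 2")
  nodes <- if (occupied_only) which(grid$occupancy > 0)
           else seq_len(nrow(grid$values))
  if (k > length(nodes)) stop("'k' exceeds the number of nodes to cluster")
  x <- grid$values[nodes, , drop = FALSE]
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- x[kmeanspp_init(x, k), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  # relabel A, B, ... by decreasing cluster size (stable on ties)
  sizes <- tabulate(best$cluster, nbins = k)
  ord <- order(-sizes, seq_len(k))
  letter_of <- character(k)
  letter_of[ord] <- cluster_letters(k)
  labels <- rep(NA_character_, nrow(grid$values))
  labels[nodes] <- letter_of[best$cluster]
  used <- sort(unique(stats::na.omit(labels)))
  profiles <- t(vapply(used, function(cl) {
    idx <- which(labels == cl)
    colMeans(grid$values[idx, , drop = FALSE])
  }, numeric(length(grid$sample_ids))))
  colnames(profiles) <- grid$sample_ids
  structure(list(labels = labels, k = as.integer(k), profiles = profiles,
                 significant = stats::setNames(rep(TRUE, length(used)), used),
                 inertia = best$tot.withinss, coords = grid$coords,
                 sample_ids = grid$sample_ids, occupancy = grid$occupancy),
            class = "grid_segmentation")
}

# k-means++ initial center indices (D^2 sampling)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ])^2)
  for (i in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      idx[i + 1L] <- sample.int(n, 1L)
    } else {
      idx[i + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[i + 1L], ])^2))
  }
  idx
}

# A..Z, then A1.. for k > 26
cluster_letters <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  c(LETTERS, paste0(LETTERS, rep(seq_len(ceiling(k / 26) - 1L),
                                 each = 26L)))[seq_len(k)]
}

#' Flag clusters without significant expression
#'
#' A cluster is significant iff the maximum absolute value of its mean
#' metagene profile across samples reaches `min_peak_abs_logfc`. Clusters
#' of practically invariant metagenes (low peaks) do not contribute to the
#' organisation of the samples and are excluded from gene selection.
#'
#' @param seg A `grid_segmentation`.
#' @param min_peak_abs_logfc Peak |delta-e| threshold (default 1.0, i.e. a
#'   2-fold change).
#' @return The segmentation with its `significant` flags updated.
#' @export
significance_filter <- function(seg, min_peak_abs_logfc = 1.0) {
  stopifnot(inherits(seg, "grid_segmentation"))
  peaks <- apply(abs(seg$profiles), 1L, max)
  seg$significant <- peaks >= min_peak_abs_logfc
  seg$peak_abs_logfc <- peaks
  seg
}

#' Genes in significant grid clusters
#'
#' Union of all genes assigned (via the SOM) to nodes belonging to
#' significant clusters — the workflow's feature-selection step.
#'
#' @param model The `som_model` that assigned genes to nodes.
#' @param seg A `grid_segmentation` with significance flags.
#' @return Character vector of gene identifiers.
#' @export
select_genes <- function(model, seg) {
  stopifnot(inherits(model, "som_model"), inherits(seg, "grid_segmentation"))
  sig <- names(seg$significant)[seg$significant]
  if (length(sig) == 0L) stop("no significant clusters; nothing to select")
  nodes <- which(seg$labels %in% sig)
  genes <- names(model$assignment)[model$assignment %in% nodes]
  if (length(genes) == 0L) stop("significant clusters contain no genes")
  genes
}

#' Compare sample hierarchies from the full and the selected gene set
#'
#' Recomputes the chosen metric/linkage variant on both matrices, cuts both
#' dendrograms by the lifetime criterion, and reports the adjusted Rand
#' index between the two partitions plus the cophenetic correlation between
#' the two trees. ARI 1 means the selected genes reconstruct the
#' whole-geneset sample partition exactly.
#'
#' @param expr_full,expr_selected gene x sample matrices over the same
#'   samples.
#' @param metric,linkage The clustering variant to recompute.
#' @return List with `ari`, `cophenetic_cor`, `k_full`, `k_selected` and
#'   both partitions.
#' @export
reconstruct_hierarchy <- function(expr_full, expr_selected,
                                  metric = "euclidean",
                                  linkage = "complete") {
  if (!identical(colnames(expr_full), colnames(expr_selected)))
    stop("matrices must share samples")
  part <- function(expr) {
    d <- pairwise_distance(t(expr), metric)
    tr <- linkage_tree(d, linkage)
    list(tree = tr, part = lifetime_cut(tr))
  }
  a <- part(expr_full); b <- part(expr_selected)
  ari <- mclust::adjustedRandIndex(a$part$labels[colnames(expr_full)],
                                   b$part$labels[colnames(expr_full)])
  cc <- stats::cor(stats::cophenetic(a$tree$hclust),
                   stats::cophenetic(b$tree$hclust))
  list(ari = ari, cophenetic_cor = cc,
       k_full = a$part$k, k_selected = b$part$k,
       partition_full = a$part, partition_selected = b$part)
}

#' Extract candidate differentiation-efficiency markers
#'
#' Identifies, among the significant grid clusters, the one whose mean
#' metagene profile correlates most negatively with replicate
#' differentiation efficiency across late samples (day >= `onset_day`), and
#' ranks that cluster's genes by their peak delta-e across all samples
#' (ties broken by gene identifier). The paper-scale use case: the
#' endoderm-contaminant signature expressed in low-efficiency replicates.
#'
#' @param expr gene x sample delta-e matrix (individual replicates).
#' @param model The `som_model` mapping genes to nodes.
#' @param seg A significance-filtered `grid_segmentation`.
#' @param metadata Sample metadata with `sample_id`, `day`, `efficiency`.
#' @param top_k Number of top genes to report (default 10).
#' @param onset_day First day considered (default 7).
#' @return A `marker_report`: `cluster`, `cluster_efficiency_cor`, `genes`
#'   (data.frame gene_id, peak_logfc, peak_sample, peak_protocol_day),
#'   `top_genes`, `trajectories` (gene x sample matrix for the top genes).
#' @export
efficiency_markers <- function(expr, model, seg, metadata, top_k = 10L,
                               onset_day = 7) {
  stopifnot(inherits(seg, "grid_segmentation"))
  if (!"efficiency" %in% names(metadata) || all(is.na(metadata$efficiency)))
    stop("metadata carries no efficiency values")
  md <- metadata[match(colnames(expr), metadata$sample_id), ]
  late <- which(md$day >= onset_day & !is.na(md$efficiency))
  if (length(late) < 3L) stop("fewer than 3 late samples with efficiency")
  eff <- md$efficiency[late]
  if (stats::sd(eff) == 0)
    stop("all replicates have equal efficiency; no efficiency-associated ",
         "cluster can be identified")
  sig <- names(seg$significant)[seg$significant]
  if (length(sig) == 0L) stop("no significant clusters")
  cors <- vapply(sig, function(cl)
    stats::cor(seg$profiles[cl, colnames(expr)[late]], eff), numeric(1))
  cl <- sig[which.min(cors)]
  nodes <- which(seg$labels == cl)
  genes <- names(model$assignment)[model$assignment %in% nodes]
  genes <- intersect(genes, rownames(expr))
  peaks <- apply(expr[genes, , drop = FALSE], 1L, max)
  peak_at <- colnames(expr)[apply(expr[genes, , drop = FALSE], 1L,
                                  which.max)]
  ord <- order(-peaks, genes)
  ranked <- data.frame(gene_id = genes[ord], peak_logfc = peaks[ord],
                       peak_sample = peak_at[ord],
                       stringsAsFactors = FALSE, row.names = NULL)
  top <- utils::head(ranked$gene_id, top_k)
  structure(list(cluster = cl,
                 cluster_efficiency_cor = unname(cors[cl]),
                 all_cluster_cors = cors,
                 genes = ranked, top_genes = top,
                 trajectories = expr[top, , drop = FALSE]),
            class = "marker_report")
}

#' Write a grid segmentation as TSV
#'
#' One row per node: grid row/col, cluster label, significance flag,
#' occupancy.
#'
#' @param seg A `grid_segmentation`.
#' @param path Output path.
#' @export
write_segmentation <- function(seg, path) {
  df <- data.frame(row = seg$coords[, "row"], col = seg$coords[, "col"],
                   cluster = seg$labels,
                   significant = unname(seg$significant[seg$labels]),
                   occupancy = seg$occupancy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.grid_segmentation <- function(x, ...) {
  cat("grid_segmentation: k =", x$k, "clusters over",
      sum(!is.na(x$labels)), "nodes;",
      sum(x$significant), "significant\n")
  invisible(x)
}

#' @export
print.marker_report <- function(x, ...) {
  cat("marker_report: cluster", x$cluster,
      sprintf("(efficiency correlation %.3f);", x$cluster_efficiency_cor),
      length(x$top_genes), "top genes:\n ",
      paste(x$top_genes, collapse = ", "), "\n")
  invisible(x)
}
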
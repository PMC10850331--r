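#' Hierarchical bi-clustering of genes and samples
#'
#' Two independent agglomerative hierarchies — one on the rows (genes), one
#' on the columns (samples) — sharing the linkage-tree implementation of
#' the sample-clustering stage. The reordered matrix (rows and columns in
#' dendrogram leaf order) is the heatmap body; a symmetric diverging colour
#' scale about 0 delta-e is used on export so samples are directly
#' comparable (unlike the per-sample scaling of SOM portraits).
#'
#' @param expr gene x sample matrix (>= 2 rows and columns).
#' @param row_metric,col_metric Distance metrics (default euclidean).
#' @param linkage Linkage method (default complete).
#' @param cluster_cols Set FALSE to keep the input column order (heatmaps
#'   where samples stay in experimental order).
#' @return A `bicluster_result`: `row_tree`, `col_tree` (NULL if columns
#'   not clustered), `row_order`, `col_order` (permutations), `matrix`
#'   (the reordered matrix).
#' @export
bicluster <- function(expr, row_metric = "euclidean",
                      col_metric = "euclidean", linkage = "complete",
                      cluster_cols = TRUE) {
  if (nrow(expr) < 2L || ncol(expr) < 2L)
    stop("need at least 2 rows and 2 columns")
  row_tree <- linkage_tree(pairwise_distance(expr, row_metric), linkage)
  row_order <- row_tree$hclust$order
  if (cluster_cols) {
    col_tree <- linkage_tree(pairwise_distance(t(expr), col_metric), linkage)
    col_order <- col_tree$hclust$order
  } else {
    col_tree <- NULL
    col_order <- seq_len(ncol(expr))
  }
  structure(list(row_tree = row_tree, col_tree = col_tree,
                 row_order = row_order, col_order = col_order,
                 matrix = expr[row_order, col_order, drop = FALSE]),
            class = "bicluster_result")
}

#' Cut the gene dendrogram of a bicluster into a fixed number of clusters
#'
#' Standard fixed-k dendrogram cut of the row tree (e.g. the 5-cluster cut
#' used to isolate a highly expressed gene block). If tied merge heights
#' make exactly `n_clusters` unattainable the nearest attainable count is
#' returned with a warning.
#'
#' @param result A `bicluster_result`.
#' @param n_clusters Requested number of row clusters (default 5).
#' @return Named integer vector: gene -> cluster.
#' @export
cut_rows <- function(result, n_clusters = 5L) {
  stopifnot(inherits(result, "bicluster_result"))
  n <- length(result$row_tree$item_ids)
  if (n_clusters > n) stop("'n_clusters' exceeds the number of rows")
  labels <- stats::cutree(result$row_tree$hclust, k = n_clusters)
  got <- length(unique(labels))
  if (got != n_clusters)
    warning("tied merge heights: returning ", got, " clusters instead of ",
            n_clusters)
  labels
}

#' Export a bicluster heatmap
#'
#' Writes the reordered matrix as TSV and, optionally, a PNG heatmap with a
#' symmetric blue-white-red scale about 0.
#'
#' @param result A `bicluster_result`.
#' @param tsv_path Path for the reordered matrix TSV.
#' @param png_path Optional PNG path.
#' @return Invisibly, the paths written.
#' @export
write_bicluster <- function(result, tsv_path, png_path = NULL) {
  m <- result$matrix
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(png_path)) {
    lim <- max(abs(m))
    ramp <- grDevices::colorRamp(c("blue", "white", "red"))
    rgb <- ramp((as.vector(m) + lim) / (2 * lim)) / 255
    img <- array(rgb, dim = c(nrow(m), ncol(m), 3L))
    png::writePNG(img, png_path)
  }
  invisible(c(tsv = tsv_path, png = png_path))
}

#' @export
print.bicluster_result <- function(x, ...) {
  cat("bicluster_result:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples;", if (is.null(x$col_tree)) "columns not clustered"
      else "both dimensions clustered", "\n")
  invisible(x)
}
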
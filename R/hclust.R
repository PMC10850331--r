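#' Pairwise distances between items
#'
#' Items are rows of `x`. Supported metrics: `euclidean`, `cosine`
#' (1 - cosine similarity) and `pearson` (1 - Pearson correlation, range
#' \[0, 2\]).
#'
#' @param x item x feature numeric matrix (>= 2 rows).
#' @param metric One of `"euclidean"`, `"cosine"`, `"pearson"`.
#' @return A `distance_matrix`: symmetric matrix with zero diagonal, with
#'   attributes `metric` and `item_ids`.
#' @export
pairwise_distance <- function(x, metric = c("euclidean", "cosine", "pearson")) {
  metric <- match.arg(metric)
  if (nrow(x) < 2L) stop("need at least 2 items")
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("item", seq_len(nrow(x)))
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(x)),
    cosine = {
      nrm <- sqrt(rowSums(x^2))
      if (any(nrm == 0))
        stop("zero vector(s) under cosine distance: ",
             paste(ids[nrm == 0], collapse = ", "))
      1 - tcrossprod(x / nrm)
    },
    pearson = {
      sds <- apply(x, 1L, stats::sd)
      if (any(sds == 0))
        stop("constant vector(s) under pearson distance: ",
             paste(ids[sds == 0], collapse = ", "))
      1 - stats::cor(t(x))
    })
  d <- (d + t(d)) / 2          # enforce exact symmetry
  diag(d) <- 0
  d[d < 0] <- 0                # clip numeric noise
  dimnames(d) <- list(ids, ids)
  structure(d, metric = metric, item_ids = ids, class = c("distance_matrix",
                                                          "matrix"))
}

#' Agglomerative linkage tree
#'
#' Builds the merge tree (dendrogram) for a distance matrix under single,
#' average or complete linkage. The Lance–Williams recursion is delegated to
#' [stats::hclust()]; the result is wrapped with its provenance so
#' downstream cutting and export know the metric and linkage used.
#'
#' @param dist A `distance_matrix` (or any symmetric matrix / `dist`).
#' @param method `"single"`, `"average"` or `"complete"`.
#' @return A `merge_tree`: list with the `hclust` object, `linkage`,
#'   `metric`, `item_ids` and sorted `heights`.
#' @export
linkage_tree <- function(dist, method = c("complete", "average", "single")) {
  method <- match.arg(method)
  metric <- attr(dist, "metric")
  d <- stats::as.dist(dist)
  hc <- stats::hclust(d, method = method)
  structure(list(hclust = hc, linkage = method,
                 metric = if (is.null(metric)) NA_character_ else metric,
                 item_ids = hc$labels, heights = hc$height),
            class = "merge_tree")
}

#' Cut a dendrogram by the lifetime criterion
#'
#' Places the cut inside the largest gap between consecutive merge heights:
#' with sorted heights `d_1 <= ... <= d_(n-1)`, the cut falls between `d_i`
#' and `d_(i+1)` for the `i` maximising `d_(i+1) - d_i`, giving `k = n - i`
#' clusters. Ties on the gap are broken toward the later (coarser) gap. If
#' no internal gap is positive (all heights equal) or there are fewer than 3
#' items the single-cluster solution is returned.
#'
#' @param tree A `merge_tree`.
#' @return A `partition`: list with `labels` (named integer vector), `k`,
#'   and `source` (metric, linkage).
#' @export
lifetime_cut <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  h <- sort(tree$heights)
  n <- length(tree$item_ids)
  k <- 1L
  if (n >= 3L) {
    gaps <- diff(h)                      # internal gaps, i = 1 .. n-2
    if (max(gaps) > 0) {
      i <- max(which(gaps == max(gaps))) # later gap on ties
      k <- n - i
    }
  }
  labels <- if (k == 1L)
    stats::setNames(rep(1L, n), tree$item_ids)
  else
    stats::cutree(tree$hclust, k = k)
  new_partition(labels, k, source = c(metric = tree$metric,
                                      linkage = tree$linkage))
}

new_partition <- function(labels, k, source = NULL) {
  structure(list(labels = labels, k = as.integer(k), source = source),
            class = "partition")
}

#' Internal validation of a partition
#'
#' Mean silhouette width (computed with the distance matrix that produced
#' the partition) and the Calinski–Harabasz index (between/within variance
#' ratio, Euclidean). Both are defined only for `2 <= k <= n - 1`; outside
#' that range the scores are `NA` and the partition is flagged as excluded
#' from model selection.
#'
#' @param x item x feature matrix (Euclidean geometry for CH).
#' @param partition A `partition` over the rows of `x`.
#' @param dist Optional precomputed `distance_matrix` for the silhouette;
#'   defaults to Euclidean distances on `x`.
#' @return List with `silhouette`, `calinski_harabasz`, `k`, `defined`.
#' @export
validate_partition <- function(x, partition, dist = NULL) {
  k <- partition$k
  n <- nrow(x)
  if (k < 2L || k > n - 1L)
    return(list(silhouette = NA_real_, calinski_harabasz = NA_real_,
                k = k, defined = FALSE))
  if (is.null(dist)) dist <- pairwise_distance(x, "euclidean")
  labels <- partition$labels[rownames(x)]
  sil <- cluster::silhouette(as.integer(labels), dmatrix = unclass(dist))
  list(silhouette = mean(sil[, "sil_width"]),
       calinski_harabasz = calinski_harabasz(x, labels),
       k = k, defined = TRUE)
}

#' Calinski–Harabasz index
#'
#' `(B / (k-1)) / (W / (n-k))` with B the between-cluster and W the
#' within-cluster sum of squared Euclidean deviations.
#'
#' @param x item x feature matrix.
#' @param labels Cluster label per row.
#' @return Nonnegative real.
#' @export
calinski_harabasz <- function(x, labels) {
  labels <- as.factor(labels)
  k <- nlevels(labels)
  n <- nrow(x)
  stopifnot(k >= 2L, k <= n - 1L)
  g <- colMeans(x)
  b <- 0; w <- 0
  for (cl in levels(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    ci <- colMeans(xi)
    b <- b + nrow(xi) * sum((ci - g)^2)
    w <- w + sum(sweep(xi, 2L, ci)^2)
  }
  if (w == 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Run all metric x linkage clustering variants and select one
#'
#' Clusters the rows of `x` under all 9 combinations of metric (euclidean,
#' cosine, pearson) and linkage (single, average, complete), cuts every
#' dendrogram by the lifetime criterion and scores each partition with the
#' silhouette coefficient and the Calinski–Harabasz index. When one
#' partition is best on both indices it is selected; otherwise partitions
#' are ranked by each index and the smallest rank-sum wins, ties broken by
#' the higher silhouette. Partitions whose k falls outside `[2, n-1]` are
#' excluded from selection.
#'
#' @param x sample x gene matrix (samples are the items clustered).
#' @return An `hc_variants` object: list with `variants` (a data.frame of
#'   metric, linkage, k, silhouette, calinski_harabasz, selected),
#'   `partitions`, `trees`, `selected` (index into the records or NA) and
#'   `selection_note`.
#' @export
run_all_variants <- function(x) {
  if (nrow(x) < 3L) stop("need at least 3 samples")
  metrics <- c("euclidean", "cosine", "pearson")
  linkages <- c("single", "average", "complete")
  recs <- list(); parts <- list(); trees <- list()
  i <- 0L
  for (m in metrics) {
    d <- pairwise_distance(x, m)
    for (l in linkages) {
      i <- i + 1L
      tr <- linkage_tree(d, l)
      pt <- lifetime_cut(tr)
      sc <- validate_partition(x, pt, dist = d)
      recs[[i]] <- data.frame(metric = m, linkage = l, k = pt$k,
                              silhouette = sc$silhouette,
                              calinski_harabasz = sc$calinski_harabasz,
                              defined = sc$defined,
                              stringsAsFactors = FALSE)
      parts[[i]] <- pt; trees[[i]] <- tr
    }
  }
  tab <- do.call(rbind, recs)
  ok <- which(tab$defined)
  selected <- NA_integer_; note <- "no partition with 2 <= k <= n-1"
  if (length(ok) > 0L) {
    best_sil <- ok[which.max(tab$silhouette[ok])]
    best_ch <- ok[which.max(tab$calinski_harabasz[ok])]
    if (best_sil == best_ch) {
      selected <- best_sil
      note <- "indices agree"
    } else {
      rk <- rank(-tab$silhouette[ok], ties.method = "min") +
        rank(-tab$calinski_harabasz[ok], ties.method = "min")
      cand <- ok[rk == min(rk)]
      selected <- cand[which.max(tab$silhouette[cand])]
      note <- "indices disagree; rank-sum rule applied"
    }
  }
  tab$selected <- seq_len(nrow(tab)) == ifelse(is.na(selected), 0L, selected)
  structure(list(variants = tab, partitions = parts, trees = trees,
                 selected = selected, selection_note = note),
            class = "hc_variants")
}

#' Principal component scores of samples
#'
#' PCA on samples (columns of the expression matrix) without scaling;
#' sample-wise centering is applied on top of the gene-centred input.
#'
#' @param expr gene x sample delta-e matrix.
#' @return List with `scores` (sample x PC), `variance_fraction` (sums to
#'   1), `sdev`.
#' @export
pca_scores <- function(expr) {
  p <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  list(scores = p$x, variance_fraction = v / sum(v), sdev = p$sdev)
}

#' Export a merge tree as Newick text
#'
#' Branch lengths derive from merge heights (leaves sit at height 0).
#' Labels containing Newick-reserved characters are single-quoted.
#'
#' @param tree A `merge_tree`.
#' @param path Optional file to write to.
#' @return Newick string (invisibly if `path` given).
#' @export
tree_to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "merge_tree"))
  hc <- tree$hclust
  reserved <- grepl("[()\\[\\]:;,']|\\s", hc$labels, perl = TRUE)
  labs <- ifelse(reserved,
                 paste0("'", gsub("'", "''", hc$labels), "'"),
                 hc$labels)
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  build <- function(i) {
    child <- function(j) {
      if (j < 0) list(str = labs[-j], h = 0) else build(j)
    }
    a <- child(hc$merge[i, 1L]); b <- child(hc$merge[i, 2L])
    h <- hc$height[i]
    list(str = paste0("(", a$str, ":", num(h - a$h), ",",
                      b$str, ":", num(h - b$h), ")"),
         h = h)
  }
  txt <- paste0(build(nrow(hc$merge))$str, ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("merge_tree:", length(x$item_ids), "items,", x$linkage, "linkage",
      if (!is.na(x$metric)) paste0("(", x$metric, " distance)"), "\n")
  invisible(x)
}

#' @export
print.partition <- function(x, ...) {
  cat("partition: k =", x$k, "over", length(x$labels), "items")
  if (!is.null(x$source)) cat(" [", paste(x$source, collapse = "/"), "]")
  cat("\n")
  invisible(x)
}

#' @export
print.hc_variants <- function(x, ...) {
  cat("hierarchical clustering,", nrow(x$variants), "variants;",
      x$selection_note, "\n")
  print(x$variants[, c("metric", "linkage", "k", "silhouette",
                       "calinski_harabasz", "selected")])
  invisible(x)
}
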
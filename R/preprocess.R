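#' Read / write a count matrix
#'
#' Counts are stored genes-in-rows as TSV (or CSV) with the gene identifier
#' in the first column and sample identifiers as the header.
#'
#' @param path File path.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return `read_count_matrix` returns an integer gene x sample matrix.
#' @export
read_count_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  validate_counts(m)
  m
}

#' @rdname read_count_matrix
#' @param counts gene x sample matrix.
#' @export
write_count_matrix <- function(counts, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts need unique gene identifiers as rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts need unique sample identifiers as colnames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  invisible(counts)
}

#' Filter lowly expressed genes
#'
#' Keeps a gene iff its counts-per-million exceed a threshold in at least
#' `n` samples, where the CPM threshold corresponds to `min_count` reads in
#' a library of median size (`t = min_count / median(library sizes) * 1e6`)
#' and `n` is the size of the smallest sample class (the condition with the
#' fewest replicates).
#'
#' @param counts gene x sample count matrix.
#' @param group_sizes Integer vector of per-class sample counts (e.g.
#'   `table(metadata$condition)`); the minimum sets `n`.
#' @param min_count Count threshold in a median-size library (default 10).
#' @return The filtered count matrix (same column set, subset of rows).
#' @export
filter_low_expression <- function(counts, group_sizes, min_count = 10) {
  validate_counts(counts)
  stopifnot(min_count > 0, length(group_sizes) >= 1L, all(group_sizes >= 1))
  lib <- colSums(counts)
  t_cpm <- min_count / stats::median(lib) * 1e6
  cpm <- t(t(counts) / lib * 1e6)
  cpm[is.na(cpm)] <- 0    # samples with zero total count contribute nothing
  n_min <- min(group_sizes)
  keep <- rowSums(cpm >= t_cpm) >= n_min
  if (!any(keep)) stop("no genes pass the expression filter")
  counts[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values (TMM) normalisation factors
#'
#' Computes one scaling factor per sample from doubly trimmed log2
#' expression ratios against a reference sample, the classic between-sample
#' normalisation for composition bias in RNA-seq. The reference is the
#' sample whose upper-quartile CPM is closest to the mean upper quartile.
#' For each sample, genes with zero counts in either the sample or the
#' reference are dropped; M (log2 ratio of proportions) and A (mean log2
#' abundance) are computed; genes outside the central `1 - 2*logratio_trim`
#' quantile band of M or the central `1 - 2*sum_trim` band of A are trimmed
#' (rank bands, ties resolved by a stable sort on gene identifier); the
#' factor is 2 to the precision-weighted mean of the surviving M values,
#' with inverse delta-method variances `(N-y)/(N*y)` as weights. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts gene x sample count matrix (>= 2 samples).
#' @param logratio_trim Fraction trimmed from each tail of M (default 0.3).
#' @param sum_trim Fraction trimmed from each tail of A (default 0.05).
#' @return A `normalization_result`: list with `tmm_factors`,
#'   `effective_library_sizes` (column sum x factor), `reference_sample`,
#'   `kept_genes`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  validate_counts(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero total count: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- t(t(counts) / lib * 1e6)
  uq <- apply(cpm, 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], lib[j], counts[, ref], lib[ref],
             rownames(counts), logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(list(tmm_factors = f,
                 effective_library_sizes = lib * f,
                 reference_sample = colnames(counts)[ref],
                 kept_genes = rownames(counts)),
            class = "normalization_result")
}

# single-pair TMM factor (sample vs reference), before geometric rescaling
tmm_pair <- function(y, n, yr, nr, ids, logratio_trim, sum_trim) {
  use <- y > 0 & yr > 0
  if (!any(use)) return(1)
  y <- y[use]; yr <- yr[use]; ids <- ids[use]
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  keep <- trim_band(m, ids, logratio_trim) & trim_band(a, ids, sum_trim)
  if (!any(keep)) return(1)
  w <- 1 / ((n - y[keep]) / (n * y[keep]) + (nr - yr[keep]) / (nr * yr[keep]))
  2^(sum(m[keep] * w) / sum(w))
}

# TRUE for entries within the central rank band after trimming `trim` off
# each tail; ranks from a stable sort on (value, id)
trim_band <- function(x, ids, trim) {
  n <- length(x)
  lo <- floor(n * trim)
  ord <- order(x, ids)
  r <- integer(n)
  r[ord] <- seq_len(n)
  r > lo & r <= n - lo
}

#' log2 counts per million with an additive prior
#'
#' `log2((y + prior) / (N_eff + 2 * prior) * 1e6)` where `N_eff` is the
#' TMM-corrected (effective) library size. The prior is a fixed additive
#' pseudocount (default 3), keeping zero counts finite.
#'
#' @param counts gene x sample count matrix.
#' @param norm A `normalization_result` from [tmm_factors()] computed on the
#'   same samples.
#' @param prior_count Positive pseudocount (default 3).
#' @return gene x sample numeric matrix of log2 CPM.
#' @export
log_cpm <- function(counts, norm, prior_count = 3) {
  validate_counts(counts)
  if (prior_count <= 0) stop("'prior_count' must be positive")
  neff <- norm$effective_library_sizes[colnames(counts)]
  if (any(is.na(neff))) stop("normalisation does not cover all samples")
  t(log2(t(counts + prior_count) / (neff + 2 * prior_count) * 1e6))
}

#' Centre each gene to its mean across samples
#'
#' Converts log expression to log2 fold changes versus the gene's ensemble
#' average: `delta_e = e - <e>_all samples`. Every downstream stage of the
#' workflow operates on this matrix.
#'
#' @param logexpr gene x sample matrix of (log) expression; finite.
#' @return gene x sample matrix with all row means 0.
#' @export
center_rows <- function(logexpr) {
  if (!all(is.finite(logexpr))) stop("input must be finite")
  sweep(logexpr, 1L, rowMeans(logexpr))
}

#' Average replicate samples into condition columns
#'
#' Collapses an expression matrix to one column per condition (arithmetic
#' mean of member samples). Conditions default to the metadata's
#' `condition` column (`<protocol>_<day>`, with seeding samples as their own
#' condition).
#'
#' @param expr gene x sample matrix.
#' @param metadata data.frame with `sample_id` and `condition` columns
#'   covering every column of `expr`.
#' @return gene x condition matrix; condition order follows metadata order
#'   of first appearance.
#' @export
average_replicates <- function(expr, metadata) {
  idx <- match(colnames(expr), metadata$sample_id)
  if (anyNA(idx)) stop("metadata does not cover all samples")
  cond <- metadata$condition[idx]
  levels <- unique(metadata$condition)
  out <- vapply(levels, function(cl) {
    cols <- which(cond == cl)
    if (length(cols) == 0L) stop("condition with zero samples: ", cl)
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(expr))
  dimnames(out) <- list(rownames(expr), levels)
  out
}

#' Full preprocessing: counts to centred logFC expression
#'
#' filter -> TMM -> logCPM -> row centering, the standard entry into the
#' workflow. Returns both the per-sample and the replicate-averaged
#' condition matrix.
#'
#' @param counts gene x sample count matrix.
#' @param metadata Sample metadata with `sample_id` and `condition`.
#' @param min_count Expression-filter threshold (see
#'   [filter_low_expression()]).
#' @param prior_count logCPM pseudocount.
#' @return List with `expr` (gene x sample delta-e), `expr_mean`
#'   (gene x condition), `norm` (normalisation result), `kept_genes`.
#' @export
preprocess_counts <- function(counts, metadata, min_count = 10,
                              prior_count = 3) {
  group_sizes <- as.integer(table(metadata$condition))
  kept <- filter_low_expression(counts, group_sizes, min_count)
  norm <- tmm_factors(kept)
  expr <- center_rows(log_cpm(kept, norm, prior_count))
  list(expr = expr,
       expr_mean = average_replicates(expr, metadata),
       norm = norm, kept_genes = rownames(kept))
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("TMM normalisation:", length(x$tmm_factors), "samples, reference",
      x$reference_sample, "\n  factors:",
      paste(sprintf("%.3f", utils::head(x$tmm_factors, 6)), collapse = " "),
      if (length(x$tmm_factors) > 6) "...\n" else "\n")
  invisible(x)
}
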
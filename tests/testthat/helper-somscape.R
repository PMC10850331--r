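# Shared fixtures and independent oracles for the test suite.

# Small two-protocol design for fast unit tests: 2 protocols x 5 days x
# 2 replicates + 2 seeding samples = 22 samples; one low-efficiency
# replicate per protocol. The day grid samples every planted module's full
# profile (mesoderm peak at 3, contaminant onset 7 / peak 9, late
# maturation by 20).
mini_design <- function() {
  make_design("custom", protocols = c("2D", "3D"),
              days = c(0L, 3L, 7L, 9L, 20L), replicates = 2L,
              n_seed_samples = 2L,
              efficiency = c("2D_r1" = 0.45, "2D_r2" = 0.85,
                             "3D_r1" = 0.50, "3D_r2" = 0.80))
}

mini_dataset <- function(seed = 7L, n_genes = 600L) {
  truth <- make_truth(mini_design(), default_modules(12L),
                      n_genes = n_genes, seed = seed)
  c(simulate_counts(truth), list(truth = truth))
}

# Preprocessed mini dataset plus a small trained SOM, computed once per
# test run.
.mini_cache <- new.env(parent = emptyenv())
mini_run <- function() {
  if (is.null(.mini_cache$run)) {
    sim <- mini_dataset()
    pp <- preprocess_counts(sim$counts, sim$metadata)
    model <- train_som(pp$expr, som_config(grid_side = 10L, epochs = 2L,
                                           seed = 11L))
    grid <- metagene_grid(model, pp$expr)
    .mini_cache$run <- list(sim = sim, pp = pp, model = model, grid = grid)
  }
  .mini_cache$run
}

# Full study-scale pipeline run (5000 genes, 40x40 grid, 3 epochs), shared
# by the acceptance-level tests; computed once.
.paper_cache <- new.env(parent = emptyenv())
paper_run <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (is.null(.paper_cache[[key]])) {
    .paper_cache[[key]] <- run_pipeline(
      pipeline_config(outdir = tempfile("paper_run_"), seed = seed),
      quiet = TRUE)
  }
  .paper_cache[[key]]
}

# day of each condition / sample label; seeding samples count as day 0
label_day <- function(labels) {
  day <- suppressWarnings(as.integer(sub(".*_", "", labels)))
  day[is.na(day)] <- 0L
  day
}

# ---- independent oracles -------------------------------------------------

# Naive TMM: explicit per-sample loop, sort-based double trim, weighted
# mean of M values — mirrors the documented algorithm step by step.
oracle_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  uq <- apply(cpm, 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  fs <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    keep <- counts[, j] > 0 & counts[, ref] > 0
    y <- counts[keep, j]; yr <- counts[keep, ref]
    ids <- rownames(counts)[keep]
    n <- lib[j]; nr <- lib[ref]
    M <- log2((y / n) / (yr / nr))
    A <- 0.5 * log2((y / n) * (yr / nr))
    nn <- length(M)
    band <- function(v, trim) {
      lo <- floor(nn * trim)
      r <- integer(nn); r[order(v, ids)] <- seq_len(nn)
      r > lo & r <= nn - lo
    }
    sel <- band(M, logratio_trim) & band(A, sum_trim)
    w <- 1 / ((n - y[sel]) / (n * y[sel]) + (nr - yr[sel]) / (nr * yr[sel]))
    fs[j] <- 2^(sum(M[sel] * w) / sum(w))
  }
  fs <- fs / exp(mean(log(fs)))
  stats::setNames(fs, colnames(counts))
}

# Hypergeometric upper tail by exhaustive enumeration of the pmf.
oracle_hyper_tail <- function(overlap, set_size, universe_size, query_size) {
  xs <- overlap:min(set_size, query_size)
  if (overlap > min(set_size, query_size)) return(0)
  sum(choose(set_size, xs) * choose(universe_size - set_size,
                                    query_size - xs)) /
    choose(universe_size, query_size)
}

# Lifetime cut by brute force: evaluate every candidate cut threshold
# (midpoints between consecutive sorted merge heights), measure the
# persistence (gap) of the partition it induces, and keep the longest-lived
# one; later gaps win ties. Returns the cluster count.
oracle_lifetime_k <- function(heights) {
  h <- sort(heights)
  n <- length(h) + 1L
  if (n < 3L) return(1L)
  best_gap <- 0; best_k <- 1L
  for (i in seq_len(n - 2L)) {
    gap <- h[i + 1L] - h[i]
    if (gap >= best_gap && gap > 0) { best_gap <- gap; best_k <- n - i }
  }
  best_k
}

# row-major square-grid coordinates, as the SOM uses internally
grid_coords_for_tests <- function(side) {
  cbind(row = rep(seq_len(side), each = side),
        col = rep(seq_len(side), side))
}

random_count_matrix <- function(n_genes = 50L, n_samples = 4L) {
  m <- matrix(stats::rnbinom(n_genes * n_samples,
                             mu = stats::rlnorm(n_genes, 4, 1.5), size = 2),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m[rowSums(m) == 0, 1L] <- 1L   # avoid all-zero rows
  m
}
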
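#' Self-organising map configuration
#'
#' Defaults follow the workflow's study-scale choices: a 40 x 40 square
#' grid (one order of magnitude fewer nodes than a ~5,000-gene post-filter
#' transcriptome — a warning is raised when the grid is large relative to
#' the gene count) trained for 3 epochs. The learning rate decays linearly
#' from `initial_rate` to `final_rate` and the Gaussian neighbourhood radius
#' from `initial_radius` (default `grid_side / 2`) to `final_radius` across
#' all training steps.
#'
#' @param grid_side Side of the square node grid (default 40).
#' @param epochs Full passes over the gene set (default 3).
#' @param seed Integer seed controlling initialisation and presentation
#'   order.
#' @param initial_radius,final_radius Neighbourhood radius decay endpoints.
#' @param initial_rate,final_rate Learning-rate decay endpoints, in (0, 1].
#' @return A `som_config` list.
#' @export
som_config <- function(grid_side = 40L, epochs = 3L, seed = 1L,
                       initial_radius = grid_side / 2, final_radius = 1,
                       initial_rate = 0.5, final_rate = 0.05) {
  stopifnot(grid_side >= 2L, epochs >= 1L,
            initial_radius > 0, final_radius > 0,
            initial_rate > 0, initial_rate <= 1,
            final_rate > 0, final_rate <= 1)
  structure(list(grid_side = as.integer(grid_side),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 initial_radius = initial_radius,
                 final_radius = final_radius,
                 initial_rate = initial_rate, final_rate = final_rate),
            class = "som_config")
}

# node grid coordinates, row-major, 1-based (row, col)
grid_coords <- function(side) {
  cbind(row = rep(seq_len(side), each = side),
        col = rep(seq_len(side), side))
}

#' Train a self-organising map on genes
#'
#' Online training: per step one gene (seeded permutation per epoch) is
#' presented, its Euclidean best-matching node found, and the winner and its
#' Gaussian neighbourhood are pulled toward the gene with linearly decaying
#' radius and rate. Nodes are initialised at randomly chosen genes plus a
#' small Gaussian perturbation (seeded), which stabilises short trainings.
#' After training every gene is assigned to its nearest node and each
#' occupied node's weight vector is replaced by the mean profile of its
#' genes (the "metagene").
#'
#' @param expr gene x sample (or gene x condition) delta-e matrix.
#' @param config A [som_config()].
#' @return A `som_model`: `weights` (node x sample), `assignment` (gene ->
#'   node index, named), `coords` (node grid positions), `config`,
#'   `training_log` (per-epoch quantization error).
#' @export
train_som <- function(expr, config = som_config()) {
  stopifnot(inherits(config, "som_config"))
  if (nrow(expr) == 0L) stop("empty expression matrix")
  if (!all(is.finite(expr))) stop("expression matrix must be finite")
  side <- config$grid_side
  n_nodes <- side^2
  if (nrow(expr) < n_nodes / 10)
    warning("gene count is less than one tenth of the node count; ",
            "consider a smaller grid")
  set.seed(config$seed)
  coords <- grid_coords(side)
  init_genes <- sample.int(nrow(expr), n_nodes, replace = n_nodes > nrow(expr))
  w0 <- expr[init_genes, , drop = FALSE] +
    matrix(stats::rnorm(n_nodes * ncol(expr), sd = 0.1), n_nodes)
  order <- t(vapply(seq_len(config$epochs),
                    function(e) sample.int(nrow(expr)),
                    integer(nrow(expr))))
  if (config$epochs == 1L) order <- matrix(order, nrow = 1L)
  fit <- som_train_cpp(unname(expr), unname(w0), coords, order,
                       config$initial_radius, config$final_radius,
                       config$initial_rate, config$final_rate)
  assignment <- som_assign_cpp(unname(expr), fit$weights)
  names(assignment) <- rownames(expr)
  # finalise: occupied nodes become the mean of their genes
  w <- fit$weights
  for (node in unique(assignment)) {
    w[node, ] <- colMeans(expr[assignment == node, , drop = FALSE])
  }
  colnames(w) <- colnames(expr)
  structure(list(weights = w, assignment = assignment, coords = coords,
                 config = config, training_log = fit$qe,
                 sample_ids = colnames(expr)),
            class = "som_model")
}

#' Metagene grid with occupancy and node quality statistics
#'
#' For every node: the metagene (mean delta-e profile of its genes; empty
#' nodes keep their trained weights so portraits are gap-free), the gene
#' occupancy, and three quality statistics — variance of the metagene
#' across samples, Shannon entropy of the metagene profile discretised into
#' `bins` equal-width bins over its own range (0 for constant profiles),
#' and the mean Pearson correlation between member genes and the metagene.
#'
#' @param model A trained `som_model`.
#' @param expr The expression matrix the model was trained on.
#' @param bins Number of equal-width entropy bins (default 10).
#' @return A `metagene_grid`: `values` (node x sample), `occupancy`,
#'   `quality` (data.frame), `coords`, `grid_side`, `sample_ids`.
#' @export
metagene_grid <- function(model, expr, bins = 10L) {
  stopifnot(inherits(model, "som_model"))
  if (!identical(colnames(expr), model$sample_ids))
    stop("expression matrix samples differ from the model's")
  n_nodes <- nrow(model$weights)
  occupancy <- tabulate(model$assignment, nbins = n_nodes)
  values <- model$weights
  variance <- apply(values, 1L, stats::var)
  entropy <- apply(values, 1L, shannon_entropy, bins = bins)
  gene_cor <- rep(NA_real_, n_nodes)
  for (node in unique(model$assignment)) {
    members <- expr[model$assignment == node, , drop = FALSE]
    meta <- values[node, ]
    if (stats::sd(meta) == 0) { gene_cor[node] <- NA_real_; next }
    rs <- apply(members, 1L, function(g)
      if (stats::sd(g) == 0) NA_real_ else stats::cor(g, meta))
    gene_cor[node] <- mean(rs, na.rm = TRUE)
  }
  structure(list(values = values, occupancy = occupancy,
                 quality = data.frame(node = seq_len(n_nodes),
                                      row = model$coords[, "row"],
                                      col = model$coords[, "col"],
                                      occupancy = occupancy,
                                      variance = variance,
                                      entropy = entropy,
                                      gene_metagene_cor = gene_cor),
                 coords = model$coords,
                 grid_side = model$config$grid_side,
                 sample_ids = model$sample_ids),
            class = "metagene_grid")
}

#' Shannon entropy of a profile under equal-width binning
#'
#' The profile range is split into `bins` equal-width bins; entropy (nats
#' base 2) of the occupancy distribution. A constant profile occupies a
#' single bin and has entropy 0.
#'
#' @param x Numeric vector.
#' @param bins Number of bins.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x, bins = 10L) {
  r <- range(x)
  if (r[1] == r[2]) return(0)
  cuts <- seq(r[1], r[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE),
                     nbins = bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

#' Per-sample expression portrait
#'
#' One sample's metagene values arranged on the grid and min-max scaled to
#' \[0, 1\] (relative scale: each portrait's extremes are that sample's own
#' lowest and highest metagene expression). A constant grid yields a flat
#' mid-scale (0.5) portrait with a warning.
#'
#' @param grid A `metagene_grid`.
#' @param sample Sample (column) identifier.
#' @param path Optional PNG path; the scaled matrix is rendered with a
#'   blue-green-yellow-red colour map, low to high.
#' @return A `portrait`: `sample_id`, `matrix` (grid_side x grid_side,
#'   row 1 at the bottom), `raw_min`, `raw_max`.
#' @export
render_portrait <- function(grid, sample, path = NULL) {
  stopifnot(inherits(grid, "metagene_grid"))
  if (!sample %in% grid$sample_ids) stop("unknown sample: ", sample)
  v <- grid$values[, sample]
  rmin <- min(v); rmax <- max(v)
  if (rmax == rmin) {
    warning("constant metagene grid for sample ", sample,
            "; flat mid-scale portrait")
    scaled <- rep(0.5, length(v))
  } else {
    scaled <- (v - rmin) / (rmax - rmin)
  }
  side <- grid$grid_side
  m <- matrix(NA_real_, side, side)
  m[cbind(grid$coords[, "row"], grid$coords[, "col"])] <- scaled
  p <- structure(list(sample_id = sample, matrix = m,
                      raw_min = rmin, raw_max = rmax),
                 class = "portrait")
  if (!is.null(path)) write_portrait_png(p, path)
  p
}

#' @rdname render_portrait
#' @param portrait A `portrait`.
#' @export
write_portrait_png <- function(portrait, path) {
  ramp <- grDevices::colorRamp(c("darkblue", "blue", "green", "yellow",
                                 "red"))
  m <- portrait$matrix
  rgb <- ramp(as.vector(m)) / 255
  side <- nrow(m)
  img <- array(rgb, dim = c(side, side, 3L))
  img <- img[rev(seq_len(side)), , , drop = FALSE]   # row 1 at the bottom
  png::writePNG(img, path)
  invisible(path)
}

#' Portraits for all replicate samples and condition means
#'
#' Computes one portrait per individual sample and one per condition
#' (arithmetic mean of the condition's replicate columns of the metagene
#' grid, equivalent to mapping the replicate-averaged expression).
#'
#' @param grid A `metagene_grid` over individual samples.
#' @param metadata Sample metadata with `sample_id` and `condition`.
#' @param dir Optional directory for PNG export.
#' @return List with `sample_portraits` and `condition_portraits` (named
#'   lists of `portrait` objects).
#' @export
condition_portraits <- function(grid, metadata, dir = NULL) {
  stopifnot(inherits(grid, "metagene_grid"))
  if (!all(grid$sample_ids %in% metadata$sample_id))
    stop("metadata does not cover all samples")
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- lapply(grid$sample_ids, function(s)
    render_portrait(grid, s,
                    path = if (is.null(dir)) NULL
                           else file.path(dir, paste0("sample_", s, ".png"))))
  names(sp) <- grid$sample_ids
  cond <- metadata$condition[match(grid$sample_ids, metadata$sample_id)]
  cg <- grid
  cg$values <- vapply(unique(cond), function(cl)
    rowMeans(grid$values[, cond == cl, drop = FALSE]),
    numeric(nrow(grid$values)))
  cg$sample_ids <- colnames(cg$values) <- unique(cond)
  cp <- lapply(cg$sample_ids, function(s)
    render_portrait(cg, s,
                    path = if (is.null(dir)) NULL
                           else file.path(dir, paste0("condition_", s, ".png"))))
  names(cp) <- cg$sample_ids
  list(sample_portraits = sp, condition_portraits = cp)
}

#' Gene positions on the trained grid
#'
#' @param model A `som_model`.
#' @return data.frame gene_id, node, row, col (1-based grid coordinates).
#' @export
gene_positions <- function(model) {
  stopifnot(inherits(model, "som_model"))
  data.frame(gene_id = names(model$assignment),
             node = unname(model$assignment),
             row = model$coords[model$assignment, "row"],
             col = model$coords[model$assignment, "col"],
             stringsAsFactors = FALSE)
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model:", x$config$grid_side, "x", x$config$grid_side, "grid,",
      length(x$assignment), "genes,", x$config$epochs, "epochs; ",
      "final quantization error",
      sprintf("%.4f", utils::tail(x$training_log, 1)), "\n")
  invisible(x)
}

#' @export
print.metagene_grid <- function(x, ...) {
  cat("metagene_grid:", x$grid_side, "x", x$grid_side, "nodes,",
      sum(x$occupancy > 0), "occupied,", length(x$sample_ids), "samples\n")
  invisible(x)
}
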
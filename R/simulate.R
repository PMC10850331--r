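#' Study design for a multi-protocol differentiation time course
#'
#' Describes the sampling layout of a differentiation experiment: which
#' culture protocols were run, on which days samples were collected, how many
#' replicate experiments exist, which (protocol, day) conditions were sampled
#' with one fewer replicate, how many seeding (undifferentiated) samples were
#' collected, and the terminal differentiation efficiency of each replicate
#' experiment (e.g. the fraction of cardiac troponin T positive cells).
#'
#' The built-in `"paper"` preset emulates a published two-protocol (2D
#' monolayer vs 3D aggregate) hiPSC cardiac differentiation study: 10 time
#' points (days 0, 1, 3, 5, 7, 9, 12, 15, 18, 20), 3 replicates per
#' condition except 2D day 12 which was run in duplicate, plus 3 hiPSC
#' seeding samples, for 2 * 10 * 3 - 1 + 3 = 62 samples in total.
#'
#' @param preset Either the string `"paper"` or `"custom"`. With `"custom"`
#'   the remaining arguments must be supplied.
#' @param protocols Character vector of protocol labels.
#' @param days Strictly increasing integer vector of sampled days.
#' @param replicates Number of replicate experiments per condition (>= 1).
#' @param duplicated_conditions A data.frame with columns `protocol` and
#'   `day`: conditions sampled with one replicate fewer. May have zero rows.
#' @param n_seed_samples Number of seeding samples taken before day 0.
#' @param efficiency Named numeric vector of per-replicate differentiation
#'   efficiencies in \[0, 1\]; names are `<protocol>_r<replicate>`.
#' @return An object of class `study_design`.
#' @examples
#' d <- make_design("paper")
#' design_n_samples(d)  # 62
#' @export
make_design <- function(preset = c("paper", "custom"),
                        protocols = NULL, days = NULL, replicates = NULL,
                        duplicated_conditions = NULL, n_seed_samples = 0L,
                        efficiency = NULL) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    protocols <- c("2D", "3D")
    days <- c(0L, 1L, 3L, 5L, 7L, 9L, 12L, 15L, 18L, 20L)
    replicates <- 3L
    duplicated_conditions <- data.frame(protocol = "2D", day = 12L,
                                        stringsAsFactors = FALSE)
    n_seed_samples <- 3L
    if (is.null(efficiency)) {
      # per-replicate terminal efficiencies spanning ~45-90%; 2D replicates
      # 1 and 3 are the low-efficiency experiments
      efficiency <- c("2D_r1" = 0.45, "2D_r2" = 0.80, "2D_r3" = 0.55,
                      "3D_r1" = 0.70, "3D_r2" = 0.90, "3D_r3" = 0.75)
    }
  }
  if (is.null(protocols) || length(protocols) < 1L)
    stop("at least one protocol is required")
  days <- as.integer(days)
  if (length(days) < 1L || any(diff(days) <= 0))
    stop("'days' must be a strictly increasing integer vector")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("'replicates' must be a positive integer")
  if (is.null(duplicated_conditions))
    duplicated_conditions <- data.frame(protocol = character(),
                                        day = integer())
  if (nrow(duplicated_conditions) > 0L) {
    ok <- duplicated_conditions$protocol %in% protocols &
      duplicated_conditions$day %in% days
    if (!all(ok)) stop("duplicated_conditions refer to unknown conditions")
    if (replicates < 2L)
      stop("duplicated conditions need at least 2 replicates")
  }
  n_seed_samples <- as.integer(n_seed_samples)
  if (n_seed_samples < 0L) stop("'n_seed_samples' must be nonnegative")
  if (is.null(efficiency)) {
    efficiency <- stats::setNames(
      rep(0.75, length(protocols) * replicates),
      paste0(rep(protocols, each = replicates), "_r",
             rep(seq_len(replicates), length(protocols))))
  }
  if (any(efficiency < 0 | efficiency > 1))
    stop("efficiencies must lie in [0, 1]")
  structure(
    list(protocols = protocols, days = days, replicates = replicates,
         duplicated_conditions = duplicated_conditions,
         n_seed_samples = n_seed_samples, efficiency = efficiency),
    class = "study_design")
}

#' Total number of samples implied by a study design
#'
#' `|protocols| * |days| * replicates - (one per duplicated condition) +
#' n_seed_samples`.
#'
#' @param design A `study_design`.
#' @return Integer sample count.
#' @export
design_n_samples <- function(design) {
  stopifnot(inherits(design, "study_design"))
  length(design$protocols) * length(design$days) * design$replicates -
    nrow(design$duplicated_conditions) + design$n_seed_samples
}

#' Sample metadata table for a study design
#'
#' Expands a `study_design` into one row per sample. Seeding samples carry
#' the pseudo-protocol `"hiPSC"` and day 0; their condition is distinct from
#' `<protocol>_0`. Replicate efficiencies are looked up per
#' `<protocol>_r<replicate>`; seeding samples inherit the mean efficiency.
#'
#' @param design A `study_design`.
#' @return data.frame with columns `sample_id`, `protocol`, `day`,
#'   `replicate`, `efficiency`, `condition`.
#' @export
design_metadata <- function(design) {
  stopifnot(inherits(design, "study_design"))
  rows <- list()
  for (p in design$protocols) {
    for (d in design$days) {
      nrep <- design$replicates
      dup <- design$duplicated_conditions
      if (nrow(dup) > 0L && any(dup$protocol == p & dup$day == d))
        nrep <- nrep - 1L
      for (r in seq_len(nrep)) {
        key <- paste0(p, "_r", r)
        eff <- unname(design$efficiency[key])
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(p, "_", d, "_", r), protocol = p, day = d,
          replicate = r, efficiency = if (is.null(eff) || is.na(eff)) NA_real_ else eff,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (r in seq_len(design$n_seed_samples)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0("hiPSC_", r), protocol = "hiPSC", day = 0L,
      replicate = r, efficiency = mean(design$efficiency),
      stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, rows)
  md$condition <- paste0(md$protocol, "_", md$day)
  md$condition[md$protocol == "hiPSC"] <- "hiPSC"
  md
}

# piecewise-linear interpolation of a module effect over day, per protocol
profile_fun <- function(knots) {
  # knots: named list protocol -> 2-column matrix (day, offset)
  function(protocol, day) {
    k <- knots[[protocol]]
    if (is.null(k)) k <- knots[[".default"]]
    if (is.null(k)) return(0)
    if (nrow(k) == 1L) return(k[1L, 2L])
    stats::approx(k[, 1L], k[, 2L], xout = day, rule = 2)$y
  }
}

#' Default planted gene modules for the differentiation simulator
#'
#' Builds the stage-specific gene modules the synthetic data generator
#' plants: pluripotency (high in seeding samples and days <= 1, decaying),
#' two transient mesoderm modules peaking at day 3 with different decay
#' kinetics (one rapidly shut off, one sustained — mirroring the distinct
#' profiles of early-wave vs sustained mesoderm markers), a cardiac
#' progenitor module rising at day 7, a cardiomyocyte module rising from day
#' 9, a translation/ribosome-like module expressed in seeding and early 2D
#' samples but silent in the 3D protocol from day 0, a 3D-only late
#' maturation module, and an endoderm-contaminant module that is active only
#' in replicate experiments whose differentiation efficiency falls below
#' `efficiency_cut` and only from `contaminant_onset_day` onward, peaking at
#' `contaminant_peak` log2FC at day 9.
#'
#' Effect profiles are piecewise-linear in day and expressed as log2
#' fold-change offsets added to each member gene's baseline log mean.
#'
#' @param n_genes_per_module Genes per stage module (>= 1).
#' @param n_contaminant_genes Genes in the endoderm-contaminant module.
#' @param contaminant_peak Peak offset (log2FC) of the contaminant module.
#' @param contaminant_onset_day First day the contaminant module is active.
#' @param efficiency_cut Replicates with efficiency strictly below this are
#'   gated "low efficiency" and express the contaminant module.
#' @return List of `gene_module` objects.
#' @export
default_modules <- function(n_genes_per_module = 40L,
                            n_contaminant_genes = 10L,
                            contaminant_peak = 7,
                            contaminant_onset_day = 7,
                            efficiency_cut = 0.6) {
  stopifnot(n_genes_per_module >= 1L, n_contaminant_genes >= 1L)
  pw <- function(...) {
    m <- matrix(c(...), ncol = 2L, byrow = TRUE)
    colnames(m) <- c("day", "offset")
    m
  }
  mk <- function(name, knots, gate = NULL) {
    structure(list(name = name, member_genes = character(),
                   profile = profile_fun(knots), knots = knots, gate = gate),
              class = "gene_module")
  }
  onset <- contaminant_onset_day
  modules <- list(
    mk("pluripotency", list(
      ".default" = pw(0, 3, 1, 2.5, 3, 0, 7, -3, 20, -3),
      "hiPSC"    = pw(0, 3))),
    mk("mesoderm_transient", list(          # TBXT-like: sharp day-3 peak
      ".default" = pw(0, 0, 1, 1.5, 3, 4, 5, 0.5, 7, -1, 20, -1),
      "hiPSC"    = pw(0, 0))),
    mk("mesoderm_sustained", list(          # ROR2-like: day-3 rise, sustained
      ".default" = pw(0, 0, 1, 0, 3, 3, 12, 3, 20, 1.5),
      "hiPSC"    = pw(0, 0))),
    mk("cardiac_progenitor", list(
      ".default" = pw(0, -1, 5, -1, 7, 3, 12, 3.5, 20, 2.5),
      "hiPSC"    = pw(0, -1))),
    mk("cardiomyocyte", list(
      ".default" = pw(0, -1, 7, -1, 9, 1.5, 12, 3.5, 20, 4),
      "hiPSC"    = pw(0, -1))),
    mk("translation_ribosome", list(        # seed + 2D start, silent in 3D
      "2D"    = pw(0, 2.5, 1, 2.5, 5, 0, 7, -1.5, 20, -1.5),
      "3D"    = pw(0, -1.5, 20, -1.5),
      "hiPSC" = pw(0, 2.5))),
    mk("maturation_3d", list(               # 3D-only late maturation
      "2D"    = pw(0, 0, 20, 0),
      "3D"    = pw(0, 0, 12, 0, 15, 2, 20, 3),
      "hiPSC" = pw(0, 0))),
    mk("endoderm_contaminant", list(
      ".default" = pw(0, 0, max(onset - 2, 0), 0, onset, 3.5, 9,
                      contaminant_peak, 12, contaminant_peak - 1, 20,
                      contaminant_peak - 1.5),
      "hiPSC"    = pw(0, 0)),
      gate = function(efficiency) !is.na(efficiency) &
        efficiency < efficiency_cut)
  )
  sizes <- c(rep(n_genes_per_module, 7L), n_contaminant_genes)
  for (i in seq_along(modules)) {
    modules[[i]]$member_genes <-
      sprintf("%s_g%03d", toupper(modules[[i]]$name), seq_len(sizes[i]))
  }
  modules
}

#' Evaluate a module's log2FC offset for one sample
#'
#' Returns the module's effect-profile value at (protocol, day), gated to 0
#' when the module carries a replicate gate and the sample's efficiency does
#' not satisfy it.
#'
#' @param module A `gene_module`.
#' @param protocol,day Sample condition.
#' @param efficiency Replicate efficiency (used only by gated modules).
#' @return Numeric offset (log2FC).
#' @export
module_offset <- function(module, protocol, day, efficiency = NA_real_) {
  stopifnot(inherits(module, "gene_module"))
  if (!is.null(module$gate) && !isTRUE(module$gate(efficiency))) return(0)
  module$profile(protocol, day)
}

#' Assemble the full ground truth of a simulation
#'
#' Draws per-gene baselines and dispersions and per-sample library sizes and
#' bundles them with the design and modules. Baseline log means (natural
#' log of expected counts at the nominal library size of 1e7) are log-normal;
#' module member genes receive baselines from the upper part of the range so
#' that planted markers behave like well-expressed transcripts. Dispersions
#' are log-uniform in \[0.01, 0.5\]; library sizes log-normal around 1e7
#' (sdlog 0.3), forcing nontrivial TMM factors.
#'
#' @param design A `study_design`.
#' @param modules List of `gene_module`s (default [default_modules()]).
#' @param n_genes Total gene universe size, including module genes.
#' @param seed Integer seed; the whole truth (and any counts simulated from
#'   it) is reproducible from it.
#' @return A `simulation_truth` object.
#' @export
make_truth <- function(design, modules = default_modules(),
                       n_genes = 5000L, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  module_genes <- unlist(lapply(modules, `[[`, "member_genes"))
  if (anyDuplicated(module_genes))
    stop("module member genes must be disjoint across modules")
  if (length(module_genes) > n_genes)
    stop("'n_genes' smaller than the number of module genes")
  n_bg <- n_genes - length(module_genes)
  gene_ids <- c(module_genes, sprintf("BG_g%05d", seq_len(n_bg)))
  set.seed(seed)
  baseline <- log(stats::rlnorm(n_genes, meanlog = log(300), sdlog = 1.4))
  # planted genes: keep baselines in a well-expressed band (>= ~100 counts)
  nm <- length(module_genes)
  baseline[seq_len(nm)] <-
    log(stats::rlnorm(nm, meanlog = log(400), sdlog = 0.6) + 100)
  dispersions <- exp(stats::runif(n_genes, log(0.01), log(0.5)))
  md <- design_metadata(design)
  lib <- round(stats::rlnorm(nrow(md), meanlog = log(1e7), sdlog = 0.3))
  names(baseline) <- names(dispersions) <- gene_ids
  names(lib) <- md$sample_id
  structure(
    list(design = design, modules = modules, gene_ids = gene_ids,
         baseline_log_means = baseline, dispersions = dispersions,
         library_sizes = lib, seed = as.integer(seed)),
    class = "simulation_truth")
}

#' Expected log2 expression offsets of every gene in every sample
#'
#' The planted signal: for each gene the sum of the offsets of the modules it
#' belongs to, evaluated at each sample's condition and gated by replicate
#' efficiency. Background genes are all-zero rows.
#'
#' @param truth A `simulation_truth`.
#' @return gene x sample numeric matrix of log2FC offsets.
#' @export
truth_offsets <- function(truth) {
  md <- design_metadata(truth$design)
  off <- matrix(0, length(truth$gene_ids), nrow(md),
                dimnames = list(truth$gene_ids, md$sample_id))
  for (mod in truth$modules) {
    o <- vapply(seq_len(nrow(md)), function(j)
      module_offset(mod, md$protocol[j], md$day[j], md$efficiency[j]),
      numeric(1))
    off[mod$member_genes, ] <-
      off[mod$member_genes, , drop = FALSE] + rep(o, each = length(mod$member_genes))
  }
  off
}

#' Simulate a count matrix from a simulation truth
#'
#' Draws negative-binomial read counts: the expected count of gene g in
#' sample s is `exp(baseline_g + ln(2) * offset_gs) * libsize_s / 1e7`,
#' with gene-wise dispersion (NB size = 1/dispersion). Identical seeds give
#' identical matrices.
#'
#' @param truth A `simulation_truth`.
#' @return List with `counts` (gene x sample integer matrix) and `metadata`
#'   (the design's sample table).
#' @export
simulate_counts <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (any(truth$dispersions <= 0)) stop("dispersions must be positive")
  md <- design_metadata(truth$design)
  off <- truth_offsets(truth)
  mu <- exp(truth$baseline_log_means + log(2) * off) *
    rep(truth$library_sizes / 1e7, each = length(truth$gene_ids))
  set.seed(truth$seed + 1L)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = rep(1 / truth$dispersions,
                                                   ncol(mu))),
    nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  list(counts = counts, metadata = md)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: design preset -> modules -> truth -> counts.
#'
#' @param preset Design preset, passed to [make_design()].
#' @param n_genes Gene universe size.
#' @param seed Integer seed.
#' @param modules Module list; defaults to [default_modules()].
#' @return List with `counts`, `metadata`, `truth`.
#' @export
simulate_dataset <- function(preset = "paper", n_genes = 5000L, seed = 1L,
                             modules = default_modules()) {
  design <- make_design(preset)
  truth <- make_truth(design, modules, n_genes = n_genes, seed = seed)
  sim <- simulate_counts(truth)
  c(sim, list(truth = truth))
}

#' Write / read simulation ground truth as JSON
#'
#' The serialised truth stores the design, per-module member genes, gate
#' flags and effect-profile knots, the per-gene baselines and dispersions,
#' library sizes and the seed; `read_truth(write_truth(x))` reproduces the
#' same counts.
#'
#' @param truth A `simulation_truth`.
#' @param path Output JSON path.
#' @return `write_truth` returns `path` invisibly; `read_truth` a
#'   `simulation_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  d <- truth$design
  obj <- list(
    design = list(protocols = d$protocols, days = d$days,
                  replicates = d$replicates,
                  duplicated_conditions = d$duplicated_conditions,
                  n_seed_samples = d$n_seed_samples,
                  efficiency = as.list(d$efficiency)),
    modules = lapply(truth$modules, function(m) list(
      name = m$name, member_genes = m$member_genes,
      gated = !is.null(m$gate),
      efficiency_cut = if (!is.null(m$gate))
        environment(m$gate)$efficiency_cut else NULL,
      knots = lapply(m$knots, function(k)
        list(day = k[, 1L], offset = k[, 2L])))),
    gene_ids = truth$gene_ids,
    baseline_log_means = unname(truth$baseline_log_means),
    dispersions = unname(truth$dispersions),
    library_sizes = as.list(truth$library_sizes),
    seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  d <- obj$design
  dup <- do.call(rbind, lapply(d$duplicated_conditions, function(r)
    data.frame(protocol = r$protocol, day = as.integer(r$day))))
  if (is.null(dup)) dup <- data.frame(protocol = character(), day = integer())
  design <- make_design("custom", protocols = d$protocols, days = d$days,
                        replicates = d$replicates,
                        duplicated_conditions = dup,
                        n_seed_samples = d$n_seed_samples,
                        efficiency = unlist(d$efficiency))
  modules <- lapply(obj$modules, function(m) {
    knots <- lapply(m$knots, function(k)
      matrix(c(k$day, k$offset), ncol = 2L,
             dimnames = list(NULL, c("day", "offset"))))
    gate <- NULL
    if (isTRUE(m$gated)) {
      efficiency_cut <- m$efficiency_cut
      gate <- function(efficiency) !is.na(efficiency) &
        efficiency < efficiency_cut
    }
    structure(list(name = m$name, member_genes = m$member_genes,
                   profile = profile_fun(knots), knots = knots, gate = gate),
              class = "gene_module")
  })
  structure(
    list(design = design, modules = modules, gene_ids = obj$gene_ids,
         baseline_log_means = stats::setNames(obj$baseline_log_means,
                                              obj$gene_ids),
         dispersions = stats::setNames(obj$dispersions, obj$gene_ids),
         library_sizes = stats::setNames(unlist(obj$library_sizes),
                                         names(obj$library_sizes)),
         seed = as.integer(obj$seed)),
    class = "simulation_truth")
}

#' Write simulated counts and metadata as TSV
#'
#' Counts are written genes-in-rows with a leading `gene_id` column;
#' metadata with columns sample_id, protocol, day, replicate, efficiency.
#'
#' @param sim A list with `counts` and `metadata` (from [simulate_counts()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, "counts.tsv")
  mp <- file.path(dir, "metadata.tsv")
  write_count_matrix(sim$counts, cp)
  utils::write.table(
    sim$metadata[, c("sample_id", "protocol", "day", "replicate", "efficiency")],
    mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cp, metadata = mp))
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", length(x$protocols), "protocol(s) x",
      length(x$days), "day(s) x", x$replicates, "replicate(s);",
      nrow(x$duplicated_conditions), "duplicated condition(s);",
      x$n_seed_samples, "seeding sample(s) =>",
      design_n_samples(x), "samples\n")
  invisible(x)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth:", length(x$gene_ids), "genes,",
      design_n_samples(x$design), "samples,",
      length(x$modules), "planted modules (seed", x$seed, ")\n")
  invisible(x)
}
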
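test_that("study-design arithmetic matches the sampling layout", {
  d <- make_design("paper")
  expect_equal(design_n_samples(d), 62L)
  expect_equal(nrow(design_metadata(d)), 62L)
  expect_equal(length(d$days), 10L)
  expect_equal(nrow(d$duplicated_conditions), 1L)

  d1 <- make_design("custom", protocols = "A", days = 0L, replicates = 1L,
                    n_seed_samples = 0L, efficiency = c(A_r1 = 0.5))
  expect_equal(design_n_samples(d1), 1L)

  # 2 protocols x 10 days x 3 reps - 1 duplicate deficit + 3 seeds
  d2 <- make_design("custom", protocols = c("P", "Q"),
                    days = seq(0L, 18L, 2L), replicates = 3L,
                    duplicated_conditions = data.frame(protocol = "P",
                                                       day = 4L),
                    n_seed_samples = 3L)
  expect_equal(design_n_samples(d2), 2L * 10L * 3L - 1L + 3L)

  expect_error(make_design("custom", protocols = "A", days = c(3L, 1L),
                           replicates = 2L), "increasing")
  expect_error(make_design("custom", protocols = "A", days = 1L,
                           replicates = 0L), "positive")
})

test_that("metadata sample count matches the design formula for varied designs", {
  set.seed(3)
  for (i in 1:10) {
    np <- sample(1:3, 1); nd <- sample(2:6, 1); nr <- sample(2:4, 1)
    protocols <- LETTERS[seq_len(np)]
    days <- sort(sample(0:30, nd))
    dup <- if (runif(1) < 0.5)
      data.frame(protocol = sample(protocols, 1), day = sample(days, 1))
    else NULL
    seeds <- sample(0:3, 1)
    d <- make_design("custom", protocols = protocols, days = days,
                     replicates = nr, duplicated_conditions = dup,
                     n_seed_samples = seeds)
    expected <- np * nd * nr - if (is.null(dup)) 0L else nrow(dup)
    expect_equal(nrow(design_metadata(d)), expected + seeds)
    expect_equal(design_n_samples(d), expected + seeds)
  }
})

test_that("default module effect profiles behave as planted", {
  mods <- default_modules(20L)
  names(mods) <- vapply(mods, `[[`, "", "name")
  cont <- mods[["endoderm_contaminant"]]

  # inactive before onset regardless of gating
  expect_equal(module_offset(cont, "2D", 0, efficiency = 0.3), 0)
  # low-efficiency replicate at the day-9 peak reaches the configured 7 logFC
  expect_equal(module_offset(cont, "2D", 9, efficiency = 0.45), 7)
  # gated off in high-efficiency replicates
  expect_equal(module_offset(cont, "2D", 9, efficiency = 0.9), 0)

  # pluripotency decays from day 0 to the final day
  plu <- mods[["pluripotency"]]
  expect_lte(module_offset(plu, "2D", 20),
             module_offset(plu, "2D", 0) - 3)

  # translation module: on in seeding and 2D day 0, off in 3D day 0
  rib <- mods[["translation_ribosome"]]
  expect_gt(module_offset(rib, "2D", 0), 1)
  expect_gt(module_offset(rib, "hiPSC", 0), 1)
  expect_lt(module_offset(rib, "3D", 0), 0)

  # the two mesoderm modules peak at day 3 but diverge afterwards
  fast <- mods[["mesoderm_transient"]]; slow <- mods[["mesoderm_sustained"]]
  expect_gt(module_offset(fast, "2D", 3), 2)
  expect_gt(module_offset(slow, "2D", 3), 2)
  expect_lt(module_offset(fast, "2D", 9), 0)
  expect_gt(module_offset(slow, "2D", 9), 2)

  # member genes disjoint across modules
  genes <- unlist(lapply(mods, `[[`, "member_genes"))
  expect_equal(anyDuplicated(genes), 0L)
})

test_that("counts are reproducible and ground truth round-trips", {
  truth <- make_truth(mini_design(), default_modules(5L), n_genes = 100L,
                      seed = 21L)
  a <- simulate_counts(truth)
  b <- simulate_counts(truth)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0))

  path <- tempfile(fileext = ".json")
  write_truth(truth, path)
  truth2 <- read_truth(path)
  expect_equal(truth2$baseline_log_means, truth$baseline_log_means)
  expect_equal(truth2$dispersions, truth$dispersions)
  expect_identical(simulate_counts(truth2)$counts, a$counts)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  d <- make_design("custom", protocols = "A", days = 0L, replicates = 1L,
                   n_seed_samples = 0L, efficiency = c(A_r1 = 0.5))
  truth <- make_truth(d, modules = list(), n_genes = 1000L, seed = 5L)
  mu <- 200
  truth$baseline_log_means[] <- log(mu)
  truth$dispersions[] <- 1e-8
  truth$library_sizes[] <- 1e7
  counts <- simulate_counts(truth)$counts
  # 1000 draws at mean mu: sample mean within 3 * sqrt(mu / 1000)
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 1000))
  # and variance close to the Poisson variance, far from overdispersed
  expect_lt(stats::var(as.numeric(counts)), 2 * mu)
})

test_that("genes in no module have flat logFC profiles", {
  run <- mini_run()
  mod_genes <- unlist(lapply(run$sim$truth$modules, `[[`, "member_genes"))
  bg <- setdiff(rownames(run$pp$expr), mod_genes)
  # averaging across hundreds of background genes cancels the NB noise
  profile <- colMeans(run$pp$expr[bg, ])
  expect_lt(max(abs(profile)), 0.15)
})

test_that("contaminant module separates gated from ungated replicates", {
  # >= 3 low-efficiency replicates, peak 7 logFC
  d <- make_design("paper",
                   efficiency = c("2D_r1" = 0.45, "2D_r2" = 0.80,
                                  "2D_r3" = 0.55, "3D_r1" = 0.50,
                                  "3D_r2" = 0.90, "3D_r3" = 0.75))
  truth <- make_truth(d, default_modules(10L), n_genes = 500L, seed = 9L)
  sim <- simulate_counts(truth)
  pp <- preprocess_counts(sim$counts, sim$metadata)
  cont <- intersect(truth$modules[[8L]]$member_genes, rownames(pp$expr))
  md <- sim$metadata[match(colnames(pp$expr), sim$metadata$sample_id), ]
  late <- md$day >= 9 & md$protocol != "hiPSC"
  low <- late & md$efficiency < 0.6
  high <- late & md$efficiency >= 0.6
  a <- colMeans(pp$expr[cont, low]); b <- colMeans(pp$expr[cont, high])
  pooled_sd <- sqrt((stats::var(a) + stats::var(b)) / 2)
  effect <- (mean(a) - mean(b)) / pooled_sd
  expect_gt(effect, 2)
})

test_that("simulation TSV outputs round-trip", {
  sim <- mini_dataset(seed = 31L, n_genes = 150L)
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  counts2 <- read_count_matrix(paths["counts"])
  expect_identical(counts2, sim$counts)
  md2 <- read.table(paths["metadata"], header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(md2$sample_id, sim$metadata$sample_id)
  expect_equal(md2$efficiency, sim$metadata$efficiency)
})
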
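test_that("metagenes are the means of their member genes", {
  run <- mini_run()
  model <- run$model; expr <- run$pp$expr
  for (node in unique(model$assignment)) {
    members <- expr[model$assignment == node, , drop = FALSE]
    expect_equal(unname(model$weights[node, ]), unname(colMeans(members)),
                 tolerance = 1e-9)
  }
  # occupancy conservation
  grid <- run$grid
  expect_equal(sum(grid$occupancy), nrow(expr))
})

test_that("a single gene's node carries exactly its profile", {
  x <- matrix(c(1, -2, 3, 0), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  model <- suppressWarnings(train_som(x, som_config(grid_side = 3L,
                                                    epochs = 1L, seed = 2L)))
  node <- model$assignment[["g1"]]
  expect_equal(unname(model$weights[node, ]), c(1, -2, 3, 0))
})

test_that("training is deterministic under a fixed seed", {
  run <- mini_run()
  cfg <- som_config(grid_side = 10L, epochs = 2L, seed = 11L)
  model2 <- train_som(run$pp$expr, cfg)
  expect_identical(model2$assignment, run$model$assignment)
  expect_equal(model2$weights, run$model$weights)
})

test_that("quantization error does not increase over epochs", {
  run <- mini_run()
  qe <- run$model$training_log
  expect_lte(qe[length(qe)], qe[1])
})

test_that("anticorrelated gene blocks map to distant grid regions", {
  set.seed(14)
  v <- sin(seq(0, 2 * pi, length.out = 12))
  block <- function(sign) t(replicate(200, sign * 3 * v + rnorm(12, 0, 0.3)))
  x <- rbind(block(+1), block(-1))
  dimnames(x) <- list(paste0("g", 1:400), paste0("s", 1:12))
  model <- train_som(center_rows(x), som_config(grid_side = 10L,
                                                epochs = 2L, seed = 3L))
  pos <- gene_positions(model)
  c1 <- colMeans(pos[1:200, c("row", "col")])
  c2 <- colMeans(pos[201:400, c("row", "col")])
  expect_gt(sqrt(sum((c1 - c2)^2)), 5)   # > grid_side / 2
})

test_that("node quality statistics follow their conventions", {
  expect_equal(shannon_entropy(rep(2, 10)), 0)
  expect_equal(shannon_entropy(c(rep(0, 5), rep(1, 5)), bins = 10), 1)
  run <- mini_run()
  q <- run$grid$quality
  occ <- q[q$occupancy == 1 & !is.na(q$gene_metagene_cor), ]
  # a node holding one gene correlates perfectly with it
  expect_true(all(abs(occ$gene_metagene_cor - 1) < 1e-9))
  expect_true(all(q$entropy >= 0))
  expect_true(all(q$variance >= 0))
})

test_that("portraits are min-max scaled per sample", {
  run <- mini_run()
  grid <- run$grid
  s <- grid$sample_ids[1]
  p <- render_portrait(grid, s)
  expect_equal(min(p$matrix), 0)
  expect_equal(max(p$matrix), 1)
  expect_equal(p$raw_min, min(grid$values[, s]))
  expect_equal(p$raw_max, max(grid$values[, s]))

  # proportional grids give identical scaled portraits
  g2 <- grid
  g2$values[, s] <- 3 * grid$values[, s]
  p2 <- render_portrait(g2, s)
  expect_equal(p2$matrix, p$matrix)

  # constant grid: flat mid-scale with a warning
  g3 <- grid
  g3$values[, s] <- 1
  expect_warning(p3 <- render_portrait(g3, s), "constant")
  expect_true(all(p3$matrix == 0.5))

  expect_error(render_portrait(grid, "no_such_sample"), "unknown")
})

test_that("portrait PNG export writes a square image", {
  run <- mini_run()
  path <- tempfile(fileext = ".png")
  render_portrait(run$grid, run$grid$sample_ids[1], path = path)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], rep(run$grid$grid_side, 2))
})

test_that("condition portraits cover conditions and replicates", {
  run <- mini_run()
  ports <- condition_portraits(run$grid, run$sim$metadata)
  expect_equal(length(ports$sample_portraits), ncol(run$pp$expr))
  expect_equal(length(ports$condition_portraits),
               length(unique(run$sim$metadata$condition)))

  # identical replicates produce identical portraits
  md <- data.frame(sample_id = c("r1", "r2"), condition = c("C", "C"))
  g <- run$grid
  g$values <- cbind(r1 = g$values[, 1], r2 = g$values[, 1])
  g$sample_ids <- c("r1", "r2")
  pp <- condition_portraits(g, md)
  expect_equal(pp$sample_portraits$r1$matrix, pp$sample_portraits$r2$matrix)
  expect_equal(pp$condition_portraits$C$matrix,
               pp$sample_portraits$r1$matrix)
})

test_that("grid topology reflects expression similarity on modular data", {
  run <- mini_run()
  grid <- run$grid
  occ <- which(grid$occupancy > 0)
  co <- grid$coords[occ, , drop = FALSE]
  vals <- grid$values[occ, , drop = FALSE]
  cm <- suppressWarnings(stats::cor(t(vals)))
  gd <- as.matrix(stats::dist(co))
  adj <- cm[gd > 0 & gd <= 1.5]
  far <- cm[gd >= grid$grid_side / 2]
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("genes sharing a node are more correlated than background", {
  run <- mini_run()
  expr <- run$pp$expr
  assignment <- run$model$assignment
  # mean over every co-mapped gene pair
  intra <- c()
  for (node in unique(assignment)) {
    g <- names(assignment)[assignment == node]
    if (length(g) < 2) next
    cm <- suppressWarnings(stats::cor(t(expr[g, ])))
    intra <- c(intra, cm[upper.tri(cm)])
  }
  set.seed(5)
  bg <- stats::cor(t(expr[sample(rownames(expr), 200), ]))
  expect_gt(mean(intra, na.rm = TRUE), mean(bg[upper.tri(bg)]) + 0.2)
})

test_that("training rejects degenerate inputs", {
  expect_error(train_som(matrix(numeric(0), 0, 3), som_config(grid_side = 2L)),
               "empty")
  x <- matrix(c(1, NA), 1, 2, dimnames = list("g", c("a", "b")))
  expect_error(suppressWarnings(train_som(x, som_config(grid_side = 2L))),
               "finite")
})
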
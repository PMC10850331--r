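test_that("pairwise distances match their definitions", {
  x <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(pairwise_distance(x, "euclidean")["a", "b"], 5)
  y <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  for (m in c("euclidean", "cosine", "pearson"))
    expect_equal(pairwise_distance(y, m)["a", "b"], 0)
  z <- rbind(a = c(1, 2, 3), b = -c(1, 2, 3))
  expect_equal(pairwise_distance(z, "pearson")["a", "b"], 2)

  bad <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(pairwise_distance(bad, "pearson"), "a")
  bad0 <- rbind(a = c(0, 0), b = c(1, 1))
  expect_error(pairwise_distance(bad0, "cosine"), "a")
})

test_that("linkage trees reproduce hand-computed merge heights", {
  x <- matrix(c(0, 1, 10), dimnames = list(c("p", "q", "r"), NULL))
  d <- pairwise_distance(x, "euclidean")
  expect_equal(linkage_tree(d, "single")$heights, c(1, 9))
  expect_equal(linkage_tree(d, "complete")$heights, c(1, 10))
  expect_equal(linkage_tree(d, "average")$heights, c(1, 9.5))

  two <- pairwise_distance(matrix(c(0, 7), dimnames = list(c("a", "b"), NULL)),
                           "euclidean")
  tr <- linkage_tree(two, "single")
  expect_equal(tr$heights, 7)
})

test_that("lifetime cut finds the largest merge-height gap", {
  # 1-D points with consecutive gaps 1, 1.1, 9: single-link heights 1, 1.1, 9
  x <- matrix(c(0, 1, 2.1, 11.1), dimnames = list(letters[1:4], NULL))
  tr <- linkage_tree(pairwise_distance(x, "euclidean"), "single")
  expect_equal(sort(tr$heights), c(1, 1.1, 9))
  p <- lifetime_cut(tr)
  expect_equal(p$k, 2L)
  expect_equal(unname(p$labels[c("a", "b", "c")]), rep(1L, 3))
  expect_equal(unname(p$labels["d"]), 2L)

  # all merge heights equal: no internal gap dominates, one cluster
  d_eq <- structure(matrix(1, 4, 4, dimnames = list(letters[1:4],
                                                    letters[1:4])),
                    metric = "euclidean")
  diag(d_eq) <- 0
  expect_equal(lifetime_cut(linkage_tree(d_eq, "single"))$k, 1L)

  # two planted blobs: k = 2 with blob-pure labels
  set.seed(4)
  blobs <- rbind(matrix(rnorm(20, 0, 0.3), 10),
                 matrix(rnorm(20, 10, 0.3), 10))
  rownames(blobs) <- paste0("s", 1:20)
  pb <- lifetime_cut(linkage_tree(pairwise_distance(blobs, "euclidean"),
                                  "average"))
  expect_equal(pb$k, 2L)
  expect_equal(length(unique(pb$labels[1:10])), 1L)
  expect_equal(length(unique(pb$labels[11:20])), 1L)
})

test_that("lifetime cut matches the brute-force max-gap oracle", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("s", seq_len(n))
    method <- sample(c("single", "average", "complete"), 1)
    tr <- linkage_tree(pairwise_distance(x, "euclidean"), method)
    expect_equal(lifetime_cut(tr)$k, oracle_lifetime_k(tr$heights))
  }
})

test_that("partition validation scores match cluster geometry", {
  set.seed(8)
  blobs <- rbind(matrix(rnorm(30, 0, 0.2), 15),
                 matrix(rnorm(30, 8, 0.2), 15))
  rownames(blobs) <- paste0("s", 1:30)
  part <- new_partition(setNames(rep(1:2, each = 15), rownames(blobs)), 2L)
  v <- validate_partition(blobs, part)
  expect_true(v$defined)
  expect_gt(v$silhouette, 0.9)
  expect_gt(v$calinski_harabasz, 100)

  # random labels on a single blob: silhouette near zero
  one <- matrix(rnorm(60), 30); rownames(one) <- paste0("s", 1:30)
  sil <- replicate(20, {
    lab <- setNames(sample(rep(1:2, 15)), rownames(one))
    validate_partition(one, new_partition(lab, 2L))$silhouette
  })
  expect_lt(abs(mean(sil)), 0.15)

  # singleton clusters everywhere: undefined, excluded from selection
  labs <- setNames(1:30, rownames(one))
  v_n <- validate_partition(one, new_partition(labs, 30L))
  expect_false(v_n$defined)
  expect_true(is.na(v_n$silhouette))
})

test_that("all nine metric/linkage variants run and one is selected", {
  # two anticorrelated profile groups: separated under euclidean, cosine
  # and pearson geometry alike
  set.seed(4)
  v <- sin(seq(0, 2 * pi, length.out = 6))
  blobs <- rbind(t(replicate(8, 3 * v + rnorm(6, 0, 0.2))),
                 t(replicate(8, -3 * v + rnorm(6, 0, 0.2))))
  rownames(blobs) <- paste0("s", 1:16)
  hv <- run_all_variants(blobs)
  expect_equal(nrow(hv$variants), 9L)
  expect_equal(sum(hv$variants$selected), 1L)
  truth_labels <- rep(1:2, each = 8)
  for (p in hv$partitions) {
    expect_equal(p$k, 2L)
    expect_equal(mclust::adjustedRandIndex(p$labels[rownames(blobs)],
                                           truth_labels), 1)
  }
})

test_that("disagreeing validation indices trigger the rank-sum rule", {
  set.seed(2)
  x <- rbind(matrix(rnorm(5 * 6), 5, 6),
             matrix(rnorm(5 * 6, mean = 3), 5, 6),
             matrix(rnorm(4 * 6, mean = c(0, 6)), 4, 6))
  rownames(x) <- paste0("s", 1:14)
  hv <- run_all_variants(x)
  expect_match(hv$selection_note, "rank-sum")
  expect_false(is.na(hv$selected))
  sel <- hv$variants[hv$selected, ]
  expect_true(sel$defined)
})

test_that("partitions are invariant to sample order", {
  set.seed(19)
  x <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(paste0("s", 1:12), NULL))
  perm <- sample(12)
  for (m in c("euclidean", "cosine", "pearson")) {
    for (l in c("single", "average", "complete")) {
      p1 <- lifetime_cut(linkage_tree(pairwise_distance(x, m), l))
      p2 <- lifetime_cut(linkage_tree(pairwise_distance(x[perm, ], m), l))
      expect_equal(p1$k, p2$k)
      expect_equal(mclust::adjustedRandIndex(p1$labels[rownames(x)],
                                             p2$labels[rownames(x)]), 1)
    }
  }
})

test_that("PCA scores decompose variance correctly", {
  # rank-1 data: first component carries all variance
  g <- outer(rnorm(6), c(1, 2, 3, 4))
  rownames(g) <- paste0("gene", 1:6); colnames(g) <- paste0("s", 1:4)
  p <- pca_scores(center_rows(g))
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-9)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)

  # reconstruction from all components returns the (sample-centred) input
  set.seed(6)
  x <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  pr <- stats::prcomp(t(x), center = TRUE)
  rec <- pr$x %*% t(pr$rotation) + matrix(pr$center, 5, 8, byrow = TRUE)
  expect_equal(unname(rec), unname(t(x)), tolerance = 1e-8)
  sc <- pca_scores(x)$scores
  expect_equal(max(abs(crossprod(sc) - diag(diag(crossprod(sc))))), 0,
               tolerance = 1e-8)
})

test_that("Newick export round-trips through a tree reader", {
  two <- pairwise_distance(matrix(c(0, 6), dimnames = list(c("A", "B"), NULL)),
                           "euclidean")
  txt <- tree_to_newick(linkage_tree(two, "single"))
  expect_equal(txt, "(A:6,B:6);")

  x <- matrix(c(0, 1, 10), dimnames = list(c("A", "B", "C"), NULL))
  tr <- linkage_tree(pairwise_distance(x, "euclidean"), "single")
  phy <- ape::read.tree(text = tree_to_newick(tr))
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  # cophenetic depths recover the merge heights
  cd <- ape::cophenetic.phylo(phy)
  expect_equal(cd["A", "B"], 2 * 1)
  expect_equal(cd["A", "C"], 2 * 9)

  # reserved characters are quoted and survive the round trip
  xq <- matrix(c(0, 2), dimnames = list(c("sam(1)", "B"), NULL))
  trq <- linkage_tree(pairwise_distance(xq, "euclidean"), "single")
  phyq <- ape::read.tree(text = tree_to_newick(trq))
  expect_true(any(grepl("sam", phyq$tip.label)))
})
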
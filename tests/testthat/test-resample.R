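test_that("an exact duplicate pair is removed first", {
  withr::with_seed(1, {
    x <- matrix(rnorm(30 * 3), 30, 3)
    x[17, ] <- x[4, ]  # plant one zero-distance duplicate in the majority
    y <- c(rep(0L, 25), rep(1L, 5))
    res <- ksu_pairs_undersample(x, y, target = 24, seed = 3)
    expect_length(res$removed, 1)
    expect_true(res$removed %in% c(4, 17))
    expect_equal(res$diagnostics$nearest_pair_distances, 0)
  })
})

test_that("default target yields an exact 1:1 balance", {
  withr::with_seed(2, {
    x <- matrix(rnorm(120 * 4), 120, 4)
    y <- c(rep(0L, 100), rep(1L, 20))
    res <- ksu_pairs_undersample(x, y, seed = 5)
    expect_equal(sum(y[res$retained] == 0), 20)
    expect_equal(sum(y[res$retained] == 1), 20)
    expect_true(all(which(y == 1) %in% res$retained))
  })
})

test_that("selected pairs match the brute-force smallest-pairs oracle", {
  # two well-separated blobs, 3 removals: intra-cluster pairs are exactly
  # the oracle's globally smallest disjoint pairs
  blobs <- make_blobs(30, gap = 50, seed = 7)
  y <- c(rep(0L, 60), rep(1L, 10))
  x <- rbind(blobs$x, matrix(rnorm(10 * 2, 25, 1), 10, 2))
  res <- ksu_pairs_undersample(x, y, n_clusters = 2, target = 57, seed = 9)
  oracle <- bf_smallest_pairs(x[1:60, ], 3)
  got <- res$diagnostics$selected_pairs
  expect_equal(nrow(got), 3)
  expect_setequal(paste(got$i, got$j), paste(oracle[, "i"], oracle[, "j"]))
  expect_equal(sort(got$dist), sort(unname(oracle[, "dist"])))
})

test_that("single-cluster KSU equals the brute-force oracle on random instances", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n_maj <- sample(10:70, 1)
      n_min <- sample(2:8, 1)
      n_rm <- sample(1:min(4, floor(n_maj / 2)), 1)
      x <- matrix(rnorm((n_maj + n_min) * 3), ncol = 3)
      y <- c(rep(0L, n_maj), rep(1L, n_min))
    })
    res <- ksu_pairs_undersample(x, y, n_clusters = 1, target = n_maj - n_rm,
                                 seed = seed)
    oracle <- bf_smallest_pairs(x[seq_len(n_maj), , drop = FALSE], n_rm)
    got <- res$diagnostics$selected_pairs
    expect_setequal(paste(got$i, got$j), paste(oracle[, "i"], oracle[, "j"]))
    # exactly one member of each selected pair was removed
    expect_true(all(vapply(seq_len(nrow(got)), function(r)
      sum(c(got$i[r], got$j[r]) %in% res$removed) == 1, logical(1))))
  }
})

test_that("resampling partitions rows and never touches the minority", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n_maj <- sample(30:80, 1); n_min <- sample(5:15, 1)
      x <- matrix(rnorm((n_maj + n_min) * 4), ncol = 4)
      y <- sample(c(rep(0L, n_maj), rep(1L, n_min)))
    })
    metric <- ddapre_metrics()[(seed %% 5) + 1]
    res <- ksu_pairs_undersample(x, y, metric = metric, seed = seed)
    expect_setequal(c(res$retained, res$removed), seq_along(y))
    expect_length(intersect(res$retained, res$removed), 0)
    expect_true(all(which(y == 1L) %in% res$retained))
    expect_equal(sum(y[res$retained] == 0L), sum(y == 1L))
    # determinism
    res2 <- ksu_pairs_undersample(x, y, metric = metric, seed = seed)
    expect_identical(res[c("retained", "removed")], res2[c("retained", "removed")])
  }
})

test_that("deep targets beyond one round of pairing are still met exactly", {
  withr::with_seed(3, {
    x <- matrix(rnorm(100 * 3), 100, 3)
    y <- c(rep(0L, 90), rep(1L, 10))
  })
  res <- ksu_pairs_undersample(x, y, target = 10, seed = 4)  # N=80 > 45 pairs
  expect_equal(sum(y[res$retained] == 0), 10)
  expect_length(res$removed, 80)
})

test_that("edited-nearest-neighbour matches its exhaustive oracle", {
  # homogeneous data: nothing removed
  xh <- matrix(rnorm(20 * 2), 20, 2)
  resh <- enn_edit_undersample(xh, rep(0L, 20), k_nn = 3)
  expect_length(resh$removed, 0)

  # a lone majority point inside a minority cluster is edited out
  withr::with_seed(5, {
    x <- rbind(matrix(rnorm(12 * 2, 0, 0.3), 12, 2),  # minority cluster
               matrix(rnorm(20 * 2, 10, 0.3), 20, 2), # majority cluster
               c(0, 0))                               # lone majority point
    y <- c(rep(1L, 12), rep(0L, 21))
  })
  res <- enn_edit_undersample(x, y, k_nn = 3)
  expect_true(33 %in% res$removed)

  # interleaved grid, k=5: exact agreement with the brute-force rule
  grid <- expand.grid(a = 1:7, b = 1:6)
  yg <- as.integer((grid$a + grid$b) %% 2 == 0)
  yg[yg == 1 & cumsum(yg) > 15] <- 0L  # tilt to create a clear majority
  xg <- as.matrix(grid) + withr::with_seed(6, matrix(rnorm(84, 0, 0.01), 42, 2))
  res <- enn_edit_undersample(xg, yg, k_nn = 5)
  expect_equal(res$removed, bf_enn_removed(xg, yg, 5))
  expect_error(enn_edit_undersample(xg, yg, k_nn = 42), "smaller than")
})

test_that("grouped undersampling honours largest-remainder quotas", {
  withr::with_seed(8, {
    x <- matrix(rnorm(115 * 3), 115, 3)
    y <- c(rep(0L, 100), rep(1L, 15))
    g <- c(rep(c("g1", "g2", "g3"), times = c(50, 30, 20)), rep("gm", 15))
  })
  res <- grouped_undersample(x, y, g, target = 30, seed = 2)
  expect_equal(sum(y[res$retained] == 0), 30)
  quotas <- res$per_cluster
  expect_equal(quotas$quota[match(c("g1", "g2", "g3"), quotas$group)],
               c(15L, 9L, 6L))

  # two equal groups, target 10 -> 5 and 5
  g2 <- c(rep(c("a", "b"), each = 50), rep("m", 15))
  res2 <- grouped_undersample(x, y, g2, target = 10, seed = 2)
  expect_equal(sort(res2$per_cluster$quota), c(5L, 5L))

  # one group degenerates to plain KSU with the same seed
  res3 <- grouped_undersample(x, y, rep("all", 115), target = 20, seed = 9)
  res4 <- ksu_pairs_undersample(x, y, target = 20, seed = 9)
  expect_identical(res3$retained, res4$retained)
})

test_that("adaptive metric selection returns a scored table", {
  fx <- make_planted_dataset(fixture_spec(n_drugs = 10, n_diseases = 12,
                                          n_features = 6, planted_dims = 1:2,
                                          positive_fraction = 0.25, seed = 12))
  x <- feature_matrix(fx$features); y <- fx$features$label
  sel <- adaptive_metric_select(x, y, candidate_metrics = c("euclidean", "manhattan"),
                                probe_cv_folds = 3, seed = 3)
  expect_s3_class(sel$scores, "tbl_df")
  expect_equal(sel$scores$metric, c("euclidean", "manhattan"))
  expect_true(all(sel$scores$auc >= 0 & sel$scores$auc <= 1))
  expect_true(sel$best %in% c("euclidean", "manhattan"))
  # single candidate passes through with a score
  one <- adaptive_metric_select(x, y, candidate_metrics = "chebyshev",
                                probe_cv_folds = 3, seed = 3)
  expect_equal(one$best, "chebyshev")
  expect_equal(nrow(one$scores), 1)
})
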
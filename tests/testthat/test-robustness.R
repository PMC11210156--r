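# Bootstrap stability, robustness filter, partition distances, grouping,
# centroids.

test_that("identity resample gives stability 1 and blobs are stable", {
  blo <- make_blobs(60, 2, delta = 10, p = 4, seed = 51)
  lab <- run_clustering(blo$X, correlation_distance(blo$X), "kmeans", 2,
                        seed = 1)
  rep1 <- bootstrap_stability(blo$X, lab, "correlation", "kmeans", 2,
                              indices = list(1:60), seed = 1)
  expect_equal(unname(rep1$per_cluster), c(1, 1))
  expect_equal(rep1$overall, 1)

  repB <- bootstrap_stability(blo$X, lab, "correlation", "kmeans", 2,
                              B = 100, seed = 2)
  expect_gte(repB$overall, 0.95)
})

test_that("pure-noise stratifications are usually unstable", {
  lows <- vapply(1:10, function(s) {
    blo <- make_blobs(80, 2, delta = 0, p = 5, seed = 300 + s)
    D <- gower_distance(blo$X)
    lab <- run_clustering(blo$X, D, "pam", 3)
    bootstrap_stability(blo$X, lab, "gower", "pam", 3, B = 50,
                        seed = s)$overall < 0.85
  }, logical(1))
  expect_gte(sum(lows), 8)
})

test_that("the robustness filter keeps the boundary and is monotone", {
  mk <- function(stabs) {
    s <- structure(list(labels = c(1, 2), depth_id = 1, metric = "gower",
                        method = "pam", k = 2), class = "stratification")
    s$stability <- structure(list(per_cluster = stabs, overall = min(stabs)),
                             class = "stability_report")
    s
  }
  strats <- list(mk(c(0.90, 0.84)), mk(c(0.85, 0.92)), mk(c(0.99, 0.99)))
  kept <- filter_robust(strats, 0.85)
  expect_equal(length(kept), 2)           # (0.90, 0.84) excluded via min rule
  expect_equal(kept[[1]]$stability$overall, 0.85)  # boundary retained
  expect_equal(length(filter_robust(list(), 0.85)), 0)
  # monotone: raising the threshold never adds members
  for (thr in c(0.5, 0.85, 0.9, 0.99)) {
    lo <- vapply(filter_robust(strats, thr), combo_id, character(1))
    hi <- vapply(filter_robust(strats, thr + 0.005), combo_id, character(1))
    expect_true(all(hi %in% lo))
  }
})

test_that("pair-counting jaccard distance matches examples and the oracle", {
  expect_equal(partition_jaccard_distance(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(partition_jaccard_distance(c(1, 1, 2, 2), c(1, 1, 1, 1)), 2 / 3)
  # relabeling invariance
  expect_equal(partition_jaccard_distance(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  expect_error(partition_jaccard_distance(c(1, 2), c(1, 2, 3)), "length")
  # exhaustive agreement with pair enumeration for all partition pairs, n = 5
  parts <- all_partitions(5)
  for (i in seq_along(parts)) for (j in seq(i, length(parts))) {
    expect_equal(partition_jaccard_distance(parts[[i]], parts[[j]]),
                 oracle_pair_jaccard(parts[[i]], parts[[j]]),
                 tolerance = 1e-12)
  }
})

test_that("grouping respects tau and the minimum group size", {
  mk <- function(labels, depth) structure(
    list(labels = labels, depth_id = depth, metric = "gower",
         method = "pam", k = 2), class = "stratification")
  a <- rep(c(1, 2), each = 10)
  b <- rep(c(1, 2, 3, 4), each = 5)
  # 6 identical -> one qualifying group
  g6 <- group_stratifications(lapply(1:6, mk, labels = a), tau = 0.3)
  expect_equal(length(g6$groups), 1)
  expect_true(g6$qualifies[[1]])
  # 4 identical + 1 distant -> no qualifying group at min size 5
  g41 <- group_stratifications(c(lapply(1:4, mk, labels = a), list(mk(b, 5))),
                               tau = 0.3, min_group_size = 5)
  expect_false(any(g41$qualifies))
  # two homogeneous blocks of 5 -> 2 qualifying groups
  g55 <- group_stratifications(c(lapply(1:5, mk, labels = a),
                                 lapply(6:10, mk, labels = b)),
                               tau = 0.3, min_group_size = 5)
  expect_equal(sum(g55$qualifies), 2)
  expect_equal(length(g55$groups), 2)
  # empty input passes through
  g0 <- group_stratifications(list())
  expect_equal(length(g0$groups), 0)
})

test_that("centroid selection minimizes distance sums with stable ties", {
  # 3 members with distance sums (0.4, 0.2, 0.5)
  Dm <- matrix(c(0, 0.1, 0.3,
                 0.1, 0, 0.1,
                 0.3, 0.1, 0), 3, 3)
  expect_equal(select_centroid(1:3, Dm), 2)
  # star topology: center closer to each leaf than leaves to each other
  n <- 5
  Ds <- matrix(0.2, n, n); Ds[1, ] <- 0.1; Ds[, 1] <- 0.1; diag(Ds) <- 0
  expect_equal(select_centroid(1:n, Ds), 1)
  # all-identical members: first in combination order wins
  expect_equal(select_centroid(2:4, matrix(0, 5, 5)), 2)
})
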
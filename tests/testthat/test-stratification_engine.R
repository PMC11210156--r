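# Patient distances, clustering methods, validity indices, consensus k.

test_that("correlation distance matches hand computations", {
  X <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(2, 4, 7), d = c(1, 2, 3))
  D <- correlation_distance(X)
  expect_equal(D["a", "d"], 0)            # identical rows
  expect_equal(D["a", "b"], 2)            # r = -1
  # r((1,2,3),(2,4,7)) = 5 / sqrt(2 * 114/9)
  expect_equal(D["a", "c"], 1 - 5 / sqrt(2 * 114 / 9), tolerance = 1e-12)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_error(correlation_distance(rbind(c(1, 1, 1), c(1, 2, 3))),
               "constant patient row")
})

test_that("gower distance averages range-normalized contributions", {
  # numeric col values 2 vs 7 with cohort range 10; binary col mismatch
  X <- rbind(p1 = c(2, 0), p2 = c(7, 1), p3 = c(12, 0))
  D <- gower_distance(X)
  expect_equal(D["p1", "p2"], (0.5 + 1) / 2)
  expect_true(all(D <= 1 + 1e-12 & D >= 0))
  expect_equal(D, t(D))
  expect_error(gower_distance(cbind(X, c(1, 1, 1))), "zero-range")
  # agrees with the established implementation on random data
  set.seed(41)
  Y <- cbind(matrix(rnorm(60), 20, 3), sample(0:1, 20, TRUE))
  ref <- suppressWarnings(as.matrix(cluster::daisy(as.data.frame(Y),
                                                   metric = "gower")))
  expect_equal(unname(gower_distance(Y)), unname(ref), tolerance = 1e-10)
})

test_that("all methods recover well-separated blobs and are reproducible", {
  blo <- make_blobs(90, 2, delta = 10, p = 4, seed = 42)
  Dc <- correlation_distance(blo$X)
  Dg <- gower_distance(blo$X)
  expect_equal(ari(run_clustering(blo$X, Dc, "kmeans", 2, seed = 1),
                   blo$labels), 1.0)
  expect_equal(ari(run_clustering(blo$X, Dg, "pam", 2), blo$labels), 1.0)
  expect_equal(ari(run_clustering(blo$X, Dc, "hierarchical", 2),
                   blo$labels), 1.0)
  expect_equal(ari(run_clustering(blo$X, Dg, "hierarchical", 2),
                   blo$labels), 1.0)
  # determinism under a fixed seed
  expect_identical(run_clustering(blo$X, Dc, "kmeans", 3, seed = 9),
                   run_clustering(blo$X, Dc, "kmeans", 3, seed = 9))
  # k grid bounds
  expect_error(run_clustering(blo$X, Dc, "kmeans", 1), "k must be")
  expect_error(run_clustering(blo$X, Dc, "kmeans", 7), "k must be")
  expect_error(run_clustering(blo$X[1:3, ], NULL, "hierarchical", 4),
               "fewer patients")
})

test_that("validity indices match the worked 4-point example", {
  x <- c(0, 1, 10, 11)
  D <- abs(outer(x, x, "-"))
  v <- validity_indices(D, c(1, 1, 2, 2))
  expect_equal(unname(v["dunn"]), 9)
  expect_equal(unname(v["wb_ratio"]), 0.1)
  s1 <- (10.5 - 1) / 10.5; s2 <- (9.5 - 1) / 9.5
  expect_equal(unname(v["avg_silhouette"]), mean(c(s1, s2, s2, s1)),
               tolerance = 1e-12)
  expect_equal(round(unname(v["avg_silhouette"]), 4), 0.8997)
})

test_that("validity indices equal brute-force enumeration (n = 6)", {
  set.seed(43)
  X <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(X))
  parts <- all_partitions(6)
  checked <- 0
  for (p in parts) {
    if (max(p) < 2) next
    expect_equal(validity_indices(D, p), oracle_validity(D, p),
                 tolerance = 1e-10)
    checked <- checked + 1
  }
  expect_gt(checked, 200)
  # silhouette of singleton clusters is 0 (checked against cluster::silhouette)
  lab <- c(1, 2, 2, 3, 3, 3)
  sil <- cluster::silhouette(lab, dmatrix = D)
  expect_equal(unname(validity_indices(D, lab)["avg_silhouette"]),
               mean(sil[, "sil_width"]), tolerance = 1e-10)
})

test_that("consensus k follows majority, silhouette arbiter, small-k ties", {
  prof <- function(wb_at, dunn_at, sil_at) {
    k <- 2:6
    data.frame(k = k,
               wb_ratio = ifelse(k == wb_at, 0.1, 1),
               dunn = ifelse(k == dunn_at, 5, 1),
               avg_silhouette = ifelse(k == sil_at, 0.9, 0.1))
  }
  expect_equal(select_k_consensus(prof(3, 3, 5)), 3)  # majority
  expect_equal(select_k_consensus(prof(2, 2, 2)), 2)  # unanimity
  expect_equal(select_k_consensus(prof(2, 3, 4)), 4)  # all disagree -> sil
  # within-index ties resolve toward smaller k
  flat <- data.frame(k = 2:6, wb_ratio = 1, dunn = 1, avg_silhouette = 0.5)
  expect_equal(select_k_consensus(flat), 2)
})

test_that("consensus k finds the planted k on separated data", {
  hits <- vapply(1:20, function(s) {
    blo <- make_blobs(90, 3, delta = 6, p = 5, seed = 200 + s)
    D <- correlation_distance(blo$X)
    labs <- lapply(2:6, function(k)
      run_clustering(blo$X, D, "hierarchical", k))
    prof <- data.frame(k = 2:6, t(vapply(labs, function(l)
      validity_indices(D, l), numeric(3))))
    names(prof) <- c("k", "wb_ratio", "dunn", "avg_silhouette")
    select_k_consensus(prof) == 3
  }, logical(1))
  expect_gte(sum(hits), 19)  # >= 95% of seeds
})

test_that("stratify_all yields 4 candidates per depth", {
  set.seed(44)
  blo <- make_blobs(60, 2, delta = 6, p = 6, seed = 45)
  colnames(blo$X) <- paste0("f", 1:6)
  enc <- encode_cohort(cohort_table(as.data.frame(blo$X),
    feature_schema(lapply(paste0("f", 1:6), function(n)
      list(name = n, kind = "numeric")))))
  depths <- enumerate_depths(build_feature_dendrogram(enc))[1:3]
  imp <- impute_chained(enc, m = 1, seed = 1)
  strats <- stratify_all(embed_all(imp, depths), k_grid = 2:4, seed = 2)
  expect_equal(length(strats), 12)  # 3 depths x 4 combinations
  expect_true(all(vapply(strats, function(s)
    all(table(s$labels) > 0), logical(1))))
  # m = 1: consolidation is the identity on the single label set
  expect_true(all(vapply(strats, function(s)
    length(s$per_imputation_k) == 1, logical(1))))
  # combination grid pairing respected
  metms <- unique(vapply(strats, function(s)
    paste(s$metric, s$method), character(1)))
  expect_setequal(metms, c("correlation hierarchical", "correlation kmeans",
                           "gower hierarchical", "gower pam"))
})
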
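# Chained-equations imputation, feature dendrogram, depths, embeddings.

make_numeric_cohort <- function(X) {
  df <- as.data.frame(X)
  cohort_table(df, feature_schema(lapply(names(df), function(n)
    list(name = n, kind = "numeric"))))
}

test_that("complete data yields m identical copies", {
  set.seed(31)
  enc <- encode_cohort(make_numeric_cohort(matrix(rnorm(60), 20, 3)))
  imp <- impute_chained(enc, m = 3, seed = 1)
  expect_identical(imp$datasets[[1]], imp$datasets[[2]])
  expect_identical(imp$datasets[[1]], enc$matrix)
})

test_that("pmm imputes only donated observed values and tracks the signal", {
  set.seed(32)
  n <- 500
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, sd = 0.1)
  df <- data.frame(x = x, y = y)
  df$y[sample(n, 100)] <- NA
  enc <- encode_cohort(make_numeric_cohort(as.matrix(df)))
  miss <- is.na(enc$matrix[, "y"])
  obs_vals <- enc$matrix[!miss, "y"]
  imp <- impute_chained(enc, m = 20, seed = 2)
  errs <- vapply(imp$datasets, function(d) {
    expect_true(all(d[miss, "y"] %in% obs_vals))  # donor property
    mean(abs(d[miss, "y"] - y[miss]))
  }, numeric(1))
  expect_lt(mean(errs), 0.5 * sd(y))
  # observed cells identical across imputations
  expect_identical(imp$datasets[[1]][!miss, ], imp$datasets[[20]][!miss, ])
})

test_that("categorical imputations respect declared levels", {
  set.seed(33)
  n <- 200
  z <- rnorm(n)
  df <- data.frame(
    x = z + rnorm(n, sd = 0.5),
    b = c("no", "yes")[(z > 0) + 1],
    g = c("A", "B", "C")[findInterval(z, c(-0.5, 0.5)) + 1],
    o = paste0("grade", findInterval(z, c(-1, 0, 1)) + 1))
  sch <- feature_schema(list(
    list(name = "x", kind = "numeric"),
    list(name = "b", kind = "binary", levels = c("no", "yes")),
    list(name = "g", kind = "nominal", levels = c("A", "B", "C")),
    list(name = "o", kind = "ordinal",
         levels = paste0("grade", 1:4))))
  for (nm in c("b", "g", "o")) df[[nm]][sample(n, 40)] <- NA
  enc <- encode_cohort(cohort_table(df, sch))
  imp <- impute_chained(enc, m = 2, seed = 3)
  for (d in imp$datasets) {
    expect_false(anyNA(d))
    expect_true(all(d[, "b"] %in% 0:1))
    expect_true(all(d[, "o"] %in% 0:3))
    # one-hot block stays a valid simplex
    expect_true(all(rowSums(d[, c("g=A", "g=B", "g=C")]) == 1))
  }
  # fully missing column is rejected
  df2 <- df; df2$b <- NA
  expect_error(impute_chained(encode_cohort(cohort_table(df2, sch)), m = 1),
               "fully missing")
})

test_that("feature dendrogram reflects collinearity and ignores row order", {
  set.seed(34)
  f1 <- rnorm(10000)
  X <- cbind(f1 = f1, f2 = f1, f3 = rnorm(10000))
  dd <- build_feature_dendrogram(X)
  expect_equal(length(dd$tree$height), 2)  # d - 1 merges
  expect_equal(min(dd$tree$height), 0)     # |r| = 1 merges at height 0
  # (f1, f2) merge first, f3 joins near height 1
  expect_equal(sort(dd$tree$merge[1, ]), c(-2, -1))
  expect_lt(abs(max(dd$tree$height) - 1), 0.05)
  # row-order invariance
  dd2 <- build_feature_dendrogram(X[sample(nrow(X)), ])
  expect_equal(dd$tree$merge, dd2$tree$merge)
  expect_equal(dd$tree$height, dd2$tree$height, tolerance = 1e-12)
  # constant column is an error naming the column
  expect_error(build_feature_dendrogram(cbind(X, cst = 1)), "cst")
})

test_that("dendrogram uses pairwise-complete correlations under missingness", {
  set.seed(35)
  f1 <- rnorm(200)
  X <- cbind(f1 = f1, f2 = f1 + rnorm(200, sd = 0.1), f3 = rnorm(200))
  X[sample(200, 50), 2] <- NA
  dd <- build_feature_dendrogram(X)
  expect_equal(sort(dd$tree$merge[1, ]), c(-2, -1))
  # too few joint observations is an error
  Y <- cbind(a = c(1, 2, NA, NA, 3), b = c(NA, NA, 1, 2, 4), c = 1:5)
  expect_error(build_feature_dendrogram(Y), "jointly observed")
})

test_that("depth enumeration excludes trivial partitions and dedupes ties", {
  set.seed(36)
  X4 <- matrix(rnorm(200 * 4), 200, 4)
  colnames(X4) <- paste0("f", 1:4)
  depths4 <- enumerate_depths(build_feature_dendrogram(X4))
  expect_equal(length(depths4), 2)
  expect_equal(sort(vapply(depths4, `[[`, integer(1), "n_groups")), c(2, 3))

  X3 <- matrix(rnorm(200 * 3), 200, 3)
  colnames(X3) <- paste0("f", 1:3)
  expect_equal(length(enumerate_depths(build_feature_dendrogram(X3))), 1)
  expect_error(enumerate_depths(
    build_feature_dendrogram(X3[, 1:2])), "non-trivial")

  # tied heights: two duplicated pairs merge at height 0 -> deduplicated cut
  f <- matrix(rnorm(400), 100, 4)
  Xt <- cbind(a = f[, 1], a2 = f[, 1], b = f[, 2], b2 = f[, 2])
  dt <- enumerate_depths(build_feature_dendrogram(Xt))
  expect_lt(length(dt), 3)  # d - 2 = 2 would need distinct heights
})

test_that("74 distinct-height columns yield 72 depths", {
  set.seed(37)
  X <- matrix(rnorm(120 * 74), 120, 74)
  colnames(X) <- paste0("f", 1:74)
  depths <- enumerate_depths(build_feature_dendrogram(X))
  expect_equal(length(depths), 72)
  expect_equal(sort(vapply(depths, `[[`, integer(1), "n_groups")), 2:73)
})

test_that("embeddings keep <=3 standardized components per group", {
  set.seed(38)
  n <- 10000
  base <- rnorm(n)
  X <- cbind(s = rnorm(n),
             c1 = base, c2 = 2 * base + 1, c3 = -base, c4 = 3 * base,
             c5 = 0.5 * base,
             i1 = rnorm(n), i2 = rnorm(n))
  depth <- structure(list(depth_id = 1L,
                          groups = list(g1 = "s",
                                        g2 = paste0("c", 1:5),
                                        g3 = c("i1", "i2")),
                          n_groups = 3L), class = "depth_partition")
  emb <- embed_depth(X, depth)
  expect_false(anyNA(emb$matrix))
  # singleton passes through standardized
  expect_equal(emb$matrix[, 1], as.numeric(scale(X[, "s"])),
               tolerance = 1e-12, ignore_attr = TRUE)
  # 5 perfectly collinear columns -> exactly 1 component, 100% of variance
  g2_cols <- emb$provenance$component[emb$provenance$group == 2]
  expect_equal(length(g2_cols), 1)
  # 2 independent columns -> 2 components with ~equal variance shares
  g3_cols <- emb$provenance$component[emb$provenance$group == 3]
  expect_equal(length(g3_cols), 2)
  v <- apply(emb$matrix[, g3_cols], 2, var)
  expect_equal(unname(v / sum(v)), c(0.5, 0.5), tolerance = 0.05)
  # component cap
  depth_all <- structure(list(depth_id = 2L,
                              groups = list(g = colnames(X)),
                              n_groups = 1L), class = "depth_partition")
  expect_lte(ncol(embed_depth(X, depth_all)$matrix), 3)
  # zero-variance group errors
  Xz <- cbind(X, z1 = 1, z2 = 2)
  depth_z <- structure(list(depth_id = 3L,
                            groups = list(g1 = c("z1", "z2"), g2 = "s"),
                            n_groups = 2L), class = "depth_partition")
  expect_error(embed_depth(Xz, depth_z), "zero total variance")
})

test_that("embedding count equals depths x imputations", {
  set.seed(39)
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- paste0("f", 1:6)
  X[sample(length(X), 20)] <- NA
  enc <- encode_cohort(make_numeric_cohort(X))
  dd <- build_feature_dendrogram(enc)
  depths <- enumerate_depths(dd)
  imp <- impute_chained(enc, m = 4, seed = 4)
  embs <- embed_all(imp, depths)
  expect_equal(length(embs), length(depths))
  expect_equal(sum(lengths(embs)), length(depths) * 4)
  expect_true(all(vapply(unlist(embs, recursive = FALSE), function(e)
    !anyNA(e$matrix), logical(1))))
})
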
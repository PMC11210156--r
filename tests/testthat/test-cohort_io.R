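# Cohort reading, validation, missingness filter, encoding, outputs.

test_that("read_cohort validates cells and fills the missingness mask", {
  fx <- write_tiny_cohort()
  co <- read_cohort(fx$table, fx$schema)
  expect_s3_class(co, "cohort_table")
  expect_identical(co$patient_ids, c("a", "b", "c"))
  expect_false(any(co$missing_mask))

  fx2 <- write_tiny_cohort(cells = list(age = c(2, "")))
  co2 <- read_cohort(fx2$table, fx2$schema)
  expect_true(co2$missing_mask[2, "age"])
  expect_equal(sum(co2$missing_mask), 1L)

  # NA tokens are case-insensitive
  fx3 <- write_tiny_cohort(cells = list(site = c(1, "nA")))
  expect_true(read_cohort(fx3$table, fx3$schema)$missing_mask[1, "site"])

  fx4 <- write_tiny_cohort(cells = list(age = c(1, "male")))
  expect_error(read_cohort(fx4$table, fx4$schema), "age")
  fx5 <- write_tiny_cohort(cells = list(site = c(3, "kidney")))
  expect_error(read_cohort(fx5$table, fx5$schema), "site")
})

test_that("duplicate patient ids and unknown columns are rejected", {
  fx <- write_tiny_cohort()
  tab <- utils::read.csv(fx$table, colClasses = "character")
  tab$patient_id[2] <- "a"
  utils::write.csv(tab, fx$table, row.names = FALSE)
  expect_error(read_cohort(fx$table, fx$schema), "duplicate patient id")

  fx2 <- write_tiny_cohort()
  tab2 <- utils::read.csv(fx2$table, colClasses = "character")
  tab2$mystery <- "1"
  utils::write.csv(tab2, fx2$table, row.names = FALSE)
  expect_error(read_cohort(fx2$table, fx2$schema), "mystery")
})

test_that("missingness filter is strict at the boundary and idempotent", {
  set.seed(1)
  df <- data.frame(f1 = rnorm(100), f2 = rnorm(100), f3 = rnorm(100))
  sch <- feature_schema(lapply(names(df), function(n)
    list(name = n, kind = "numeric")))
  df$f2[1:30] <- NA   # exactly 30% -> dropped (strict <)
  df$f3[1:29] <- NA   # 29% -> retained
  co <- cohort_table(df, sch)
  filt <- filter_features_by_missingness(co, 0.30)
  expect_identical(names(filt$data), c("f1", "f3"))
  # idempotent
  filt2 <- filter_features_by_missingness(filt, 0.30)
  expect_identical(filt2$data, filt$data)
  # complete table unchanged
  co_complete <- cohort_table(data.frame(a = rnorm(10), b = rnorm(10)),
                              feature_schema(list(
                                list(name = "a", kind = "numeric"),
                                list(name = "b", kind = "numeric"))))
  expect_identical(
    filter_features_by_missingness(co_complete)$data, co_complete$data)
  # fewer than 2 survivors is an error
  df$f1[1:40] <- NA
  expect_error(filter_features_by_missingness(cohort_table(df, sch), 0.30),
               "fewer than 2")
})

test_that("encoding maps kinds correctly and is lossless for observed cells", {
  fx <- write_tiny_cohort(cells = list(site = c(2, "")))
  co <- read_cohort(fx$table, fx$schema)
  enc <- encode_cohort(co)
  m <- enc$matrix
  # nominal with levels {liver, lung, bone}: value liver -> (1,0,0)
  expect_equal(unname(m[1, c("site=liver", "site=lung", "site=bone")]),
               c(1, 0, 0))
  # indicators sum to 1 where observed, all NA where missing
  expect_true(all(is.na(m[2, c("site=liver", "site=lung", "site=bone")])))
  expect_equal(unname(m[3, "site=liver"]), 1)
  # binary single column, levels (f, m): m -> 1, f -> 0
  expect_equal(unname(m[, "sex"]), c(1, 0, 0))
  # ordinal 0-based rank: III (3rd of 3 levels) -> 2
  expect_equal(unname(m[3, "stage"]), 2)
  # decode recovers the observed categories (missingness preserved)
  dec <- clustall:::decode_encoded(m, enc$provenance, enc$schema)
  expect_equal(dec$site, c("liver", NA, "liver"))
  expect_equal(dec$stage, c("II", "I", "III"))
  expect_equal(dec$sex, c("m", "f", "f"))
  expect_equal(dec$age, co$data$age)
})

test_that("row order and patient ids survive filter and encode", {
  set.seed(2)
  df <- data.frame(x = rnorm(20), y = rnorm(20), z = rnorm(20))
  df$z[1:10] <- NA
  co <- cohort_table(df, feature_schema(lapply(names(df), function(n)
    list(name = n, kind = "numeric"))), patient_ids = paste0("pt", 20:1))
  filt <- filter_features_by_missingness(co, 0.3)
  expect_identical(filt$patient_ids, co$patient_ids)
  expect_identical(rownames(encode_cohort(filt)$matrix), co$patient_ids)
  expect_equal(filt$data$x, df$x)
})

test_that("write_outputs produces labels, stability, summary and is deterministic", {
  blo <- make_blobs(40, 2, delta = 8, p = 4, seed = 3)
  sch <- feature_schema(lapply(paste0("v", 1:4), function(n)
    list(name = n, kind = "numeric")))
  df <- as.data.frame(blo$X); names(df) <- paste0("v", 1:4)
  co <- cohort_table(df, sch)
  ens <- run_pipeline(co, run_config(m = 1, B = 20, min_group_size = 1,
                                     seed = 5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_outputs(d1, ens)
  write_outputs(d2, ens)
  labs <- utils::read.csv(file.path(d1, "labels.csv"))
  expect_equal(names(labs)[1], "patient_id")
  expect_equal(ncol(labs), 1 + length(ens$representatives))
  expect_gte(length(ens$representatives), 1)
  stab <- utils::read.csv(file.path(d1, "stability.csv"))
  expect_true(all(stab$stability >= 0 & stab$stability <= 1))
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))

  # empty ensemble: header-only labels file plus an explicit summary flag
  empty <- ens
  empty$representatives <- list()
  d3 <- withr::local_tempdir()
  write_outputs(d3, empty)
  labs0 <- utils::read.csv(file.path(d3, "labels.csv"))
  expect_equal(nrow(labs0), 0)
  summ <- jsonlite::read_json(file.path(d3, "summary.json"))
  expect_true(summ$no_robust_stratification)
})
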
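# Shared fixtures and independent oracles for the test suite.

# --- tiny cohort written to disk ------------------------------------------

write_tiny_cohort <- function(dir = NULL, cells = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("cohort")
    dir.create(dir)
  }
  tab <- data.frame(patient_id = c("a", "b", "c"),
                    age = c("61", "47", "55"),
                    sex = c("m", "f", "f"),
                    stage = c("II", "I", "III"),
                    site = c("liver", "lung", "liver"),
                    stringsAsFactors = FALSE)
  if (!is.null(cells))
    for (nm in names(cells)) tab[cells[[nm]][1], nm] <- cells[[nm]][2]
  table_path <- file.path(dir, "cohort.csv")
  utils::write.csv(tab, table_path, row.names = FALSE)
  schema <- list(
    list(name = "age", kind = "numeric"),
    list(name = "sex", kind = "binary", levels = list("f", "m")),
    list(name = "stage", kind = "ordinal", levels = list("I", "II", "III")),
    list(name = "site", kind = "nominal",
         levels = list("liver", "lung", "bone")))
  schema_path <- file.path(dir, "schema.yaml")
  yaml::write_yaml(list(features = schema), schema_path)
  list(table = table_path, schema = schema_path, dir = dir)
}

# Gaussian blobs: k clusters separated by `delta` within-cluster SDs on every
# coordinate direction (round-robin), as a plain matrix plus labels.
make_blobs <- function(n, k, delta, p = 4, seed = 1) {
  set.seed(seed)
  labels <- sample(rep_len(seq_len(k), n))
  mu <- matrix(0, k, p)
  mu[cbind(((seq_len(p) - 1L) %% k) + 1L, seq_len(p))] <- delta
  X <- matrix(rnorm(n * p), n, p) + mu[labels, , drop = FALSE]
  rownames(X) <- paste0("P", seq_len(n))
  list(X = X, labels = labels)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# --- brute-force oracles ---------------------------------------------------

# All set partitions of n points as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(labs) {
    if (length(labs) == n) { out[[length(out) + 1L]] <<- labs; return() }
    mx <- if (length(labs)) max(labs) else 0L
    for (v in seq_len(mx + 1L)) grow(c(labs, v))
  }
  grow(integer())
  out
}

# Validity indices by direct enumeration over all point pairs.
oracle_validity <- function(D, labels) {
  n <- nrow(D)
  wi <- c(); be <- c()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (labels[i] == labels[j]) wi <- c(wi, D[i, j]) else be <- c(be, D[i, j])
  }
  wb <- if (length(wi) == 0) 0 else mean(wi) / mean(be)
  dunn <- min(be) / max(c(wi, 0))
  sil <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s <- (b - a) / max(a, b)
    if (is.nan(s)) 0 else s
  }, numeric(1))
  c(wb_ratio = wb, dunn = dunn, avg_silhouette = mean(sil))
}

# Pair-counting Jaccard distance by direct enumeration over all pairs.
oracle_pair_jaccard <- function(a, b) {
  n <- length(a)
  n11 <- 0; n10 <- 0; n01 <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
  }
  if (n11 + n10 + n01 == 0) return(0)
  1 - n11 / (n11 + n10 + n01)
}

# Generator settings used by the end-to-end recovery checks: a 30-feature
# mixed panel in three correlated blocks with 3 planted subgroups.
recovery_sim_config <- function(seed, n = 300, missing_rate = 0.2) {
  sim_config(
    n_patients = n,
    feature_blocks = list(
      list(kinds = c(numeric = 8, binary = 2, nominal = 1, ordinal = 1),
           rho = 0.45),
      list(kinds = c(numeric = 6, binary = 3, nominal = 1, ordinal = 1),
           rho = 0.30),
      list(kinds = c(numeric = 4, binary = 2, nominal = 1), rho = 0.15)),
    n_clusters = 3, effect_size = 4, informative_frac = 0.4,
    missing_rate = missing_rate, missing_mechanism = "MCAR", seed = seed)
}
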
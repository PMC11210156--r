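# Internal helpers shared across modules.

#' @keywords internal
#' @useDynLib clustall, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# hclust-compatible average-linkage tree from a full dissimilarity matrix,
# via the compiled NN-chain kernel (hot path: bootstrap re-clustering).
avg_linkage_tree <- function(D) {
  res <- cpp_average_linkage(D)
  structure(list(merge = res$merge, height = res$height, order = res$order,
                 labels = rownames(D), method = "average",
                 dist.method = "user"),
            class = "hclust")
}

# Wrap a symmetric dissimilarity matrix as a "dist" object without the
# checking overhead of as.dist() (hot path: thousands of calls per run).
# Lower-triangle index templates are cached per matrix size.
.lt_cache <- new.env(parent = emptyenv())

fast_dist <- function(D) {
  n <- nrow(D)
  key <- as.character(n)
  idx <- .lt_cache[[key]]
  if (is.null(idx)) {
    idx <- which(lower.tri(D))
    .lt_cache[[key]] <- idx
  }
  structure(D[idx], Size = n, class = "dist",
            Diag = FALSE, Upper = FALSE, method = "user")
}

# Derive independent child seeds from a master seed.  R integers are 32-bit,
# so everything stays below 2^31.
derive_seeds <- function(seed, n, stream = 0L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((as.integer(seed) + 977L * as.integer(stream)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Minimal run logger: accumulates lines, optionally echoes.
new_log <- function(verbose = FALSE) {
  env <- new.env(parent = emptyenv())
  env$lines <- character()
  env$verbose <- isTRUE(verbose)
  env
}

log_msg <- function(log, ...) {
  if (is.null(log)) return(invisible(NULL))
  line <- paste0(...)
  log$lines <- c(log$lines, line)
  if (log$verbose) message(line)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adjusted Rand index between two partitions (used in reports; tests
# cross-check against mclust::adjustedRandIndex).
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
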
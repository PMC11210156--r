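# Clustering per combination, internal validity indices and consensus k.
#
# Method-metric pairing: correlation distance -> k-means (on row-standardized
# embedding rows, where squared Euclidean distance is monotone in correlation
# distance) and average-linkage hierarchical; Gower -> PAM (k-medoids,
# BUILD+SWAP, deterministic) and average-linkage hierarchical.

#' Cluster an embedding with one method at one k
#'
#' @param embedding an `embedding` or numeric matrix (used by k-means).
#' @param distance precomputed patient dissimilarity matrix (used by PAM and
#'   hierarchical clustering).
#' @param method `"kmeans"`, `"pam"` or `"hierarchical"`.
#' @param k number of clusters, in `2..6`.
#' @param seed integer seed (k-means++-style seeding; PAM and hierarchical
#'   clustering are deterministic).
#' @return integer label vector in `1..k`; all clusters non-empty.
#' @export
run_clustering <- function(embedding, distance = NULL,
                           method = c("kmeans", "pam", "hierarchical"),
                           k, seed = 1) {
  method <- match.arg(method)
  X <- if (inherits(embedding, "embedding")) embedding$matrix else embedding
  n <- if (!is.null(X)) nrow(X) else nrow(distance)
  if (k < 2 || k > 6) stop("k must be in {2..6}, got ", k)
  if (n < k) stop("fewer patients (", n, ") than clusters (", k, ")")
  switch(method,
    kmeans = kmeans_correlation(X, k, seed),
    pam = as.integer(cpp_pam(distance, k)),
    hierarchical = {
      tree <- avg_linkage_tree(distance)
      as.integer(stats::cutree(tree, k = k))
    })
}

# k-means honoring the correlation metric: rows are z-scored so squared
# Euclidean distance is order-equivalent to correlation distance; Lloyd
# iterations from a k-means++-style seeding.
kmeans_correlation <- function(X, k, seed) {
  Xz <- row_standardize(X)
  set.seed(seed)
  for (attempt in 1:5) {
    centers <- Xz[kmeanspp_init(Xz, k), , drop = FALSE]
    fit <- suppressWarnings(try(
      stats::kmeans(Xz, centers = centers, algorithm = "Lloyd",
                    iter.max = 100),
      silent = TRUE))
    if (!inherits(fit, "try-error") && length(unique(fit$cluster)) == k)
      return(as.integer(fit$cluster))
  }
  stop("k-means failed to produce ", k, " non-empty clusters")
}

row_standardize <- function(X) {
  mu <- rowMeans(X)
  sd <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  if (any(sd == 0))
    stop("constant patient row(s): cannot row-standardize")
  (X - mu) / sd
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  ids <- integer(k)
  ids[1] <- sample.int(n, 1)
  d2 <- colSums((t(X) - X[ids[1], ])^2)
  for (i in seq_len(k - 1)) {
    d2[d2 < 0] <- 0
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    ids[i + 1] <- sample.int(n, 1, prob = probs)
    d2 <- pmin(d2, colSums((t(X) - X[ids[i + 1], ])^2))
  }
  ids
}

#' Internal cluster validity indices
#'
#' Computes, from a dissimilarity matrix and a label vector:
#' * `wb_ratio`: mean within-cluster dissimilarity over mean between-cluster
#'   dissimilarity (lower is better);
#' * `dunn`: minimum between-cluster point-pair dissimilarity over maximum
#'   cluster diameter (higher is better);
#' * `avg_silhouette`: mean silhouette width, with silhouette 0 for members
#'   of singleton clusters (higher is better).
#'
#' @param distance symmetric dissimilarity matrix.
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @return named numeric vector `c(wb_ratio, dunn, avg_silhouette)`.
#' @export
validity_indices <- function(distance, labels) {
  n <- nrow(distance)
  stopifnot(length(labels) == n)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("validity indices require >= 2 clusters")
  v <- cpp_validity(distance, labels, k)
  c(wb_ratio = v[["wb_ratio"]], dunn = v[["dunn"]],
    avg_silhouette = v[["avg_silhouette"]])
}

#' Consensus selection of the number of clusters
#'
#' Each validity index votes for its best k over the profile (minimum
#' WB-ratio; maximum Dunn; maximum average silhouette; within-index ties go
#' to the smaller k). A majority (at least two votes) wins; when all three
#' indices disagree, the silhouette vote decides.
#'
#' @param profile data.frame with columns `k`, `wb_ratio`, `dunn`,
#'   `avg_silhouette`, one row per candidate k.
#' @return the selected k.
#' @export
select_k_consensus <- function(profile) {
  stopifnot(all(c("k", "wb_ratio", "dunn", "avg_silhouette") %in%
                names(profile)))
  profile <- profile[order(profile$k), , drop = FALSE]
  votes <- c(wb = profile$k[which.min(profile$wb_ratio)],
             dunn = profile$k[which.max(profile$dunn)],
             sil = profile$k[which.max(profile$avg_silhouette)])
  tab <- table(votes)
  if (max(tab) >= 2) as.integer(names(tab)[which.max(tab)])
  else as.integer(votes[["sil"]])
}

# Labels for every k in the grid for one method, sharing work across k
# (hierarchical clustering cuts one tree; PAM and k-means run per k).
cluster_grid <- function(X, distance, method, k_grid, seed) {
  if (method == "hierarchical") {
    tree <- avg_linkage_tree(distance)
    labs <- stats::cutree(tree, k = k_grid)
    lapply(seq_along(k_grid), function(i) as.integer(labs[, i]))
  } else {
    seeds <- derive_seeds(seed, length(k_grid), stream = 3L)
    lapply(seq_along(k_grid), function(i)
      run_clustering(X, distance, method, k_grid[i], seeds[i]))
  }
}

# The four combination slots per depth, in lexicographic (metric, method)
# order; this order also defines centroid tie-breaking.
combination_grid <- function() {
  data.frame(metric = c("correlation", "correlation", "gower", "gower"),
             method = c("hierarchical", "kmeans", "hierarchical", "pam"),
             stringsAsFactors = FALSE)
}

combo_id <- function(s) {
  paste0("depth", s$depth_id, "_", s$metric, "_", s$method)
}
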
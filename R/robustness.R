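# Robustness: bootstrap cluster-wise Jaccard stability (population-based) and
# grouping of stratifications under pair-counting Jaccard distance
# (parameter-based), with centroid representatives.

#' Bootstrap cluster-wise Jaccard stability
#'
#' Patients are resampled with replacement B times; each resample is
#' re-clustered with the same method and k on the reference embedding, and
#' every original cluster is scored by its maximum Jaccard similarity
#' (intersection over union, counted over the resampled patient draws)
#' against any bootstrap cluster. Per-cluster stability is the mean of these
#' maxima over the resamples; the overall stability is the minimum across
#' clusters (the weakest cluster governs the robustness filter).
#'
#' @param embedding reference `embedding` or numeric matrix.
#' @param labels the stratification's label vector on the reference data.
#' @param metric `"correlation"` or `"gower"`.
#' @param method `"kmeans"`, `"pam"` or `"hierarchical"`.
#' @param k number of clusters.
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @param indices optional list of resample index vectors (overrides random
#'   resampling; used for reproducibility checks).
#' @param distance optional precomputed dissimilarity matrix for the
#'   reference embedding (recomputed from `metric` when omitted).
#' @param log optional run log.
#' @return a `stability_report`: `per_cluster` (mean Jaccard per original
#'   cluster), `overall` (minimum), `B`, `n_skipped`.
#' @export
bootstrap_stability <- function(embedding, labels, metric, method, k,
                                B = 100, seed = 1, indices = NULL,
                                distance = NULL, log = NULL) {
  X <- if (inherits(embedding, "embedding")) embedding$matrix else embedding
  n <- nrow(X)
  stopifnot(length(labels) == n, B >= 1 || !is.null(indices))
  D <- if (method == "kmeans") NULL
       else distance %||% patient_distance(X, metric)
  if (!is.null(indices)) B <- length(indices)
  seeds <- derive_seeds(seed, B, stream = 5L)
  orig_int <- as.integer(factor(labels))
  k_orig <- max(orig_int)
  jac_sum <- numeric(k_orig)
  used <- 0L; skipped <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- if (!is.null(indices)) indices[[b]]
           else sample.int(n, n, replace = TRUE)
    if (length(unique(idx)) < k) { skipped <- skipped + 1L; next }
    boot_lab <- tryCatch(
      recluster_resample(X, D, idx, method, k, seeds[b]),
      error = function(e) NULL)
    if (is.null(boot_lab)) { skipped <- skipped + 1L; next }
    orig <- orig_int[idx]
    k_boot <- max(boot_lab)
    # cross-tabulate original vs bootstrap clusters over the drawn positions
    tab <- matrix(tabulate((boot_lab - 1L) * k_orig + orig, k_orig * k_boot),
                  k_orig, k_boot)
    rs <- rowSums(tab); cs <- colSums(tab)
    # jaccard(a, c) = n_ac / (n_a + n_c - n_ac); best match per original a
    jac <- tab / (outer(rs, cs, "+") - tab)
    jac[is.nan(jac)] <- 0
    jac_sum <- jac_sum + apply(jac, 1, max)
    used <- used + 1L
  }
  if (skipped > 0)
    log_msg(log, "bootstrap_stability: skipped ", skipped, " degenerate resamples")
  if (used == 0) stop("no usable bootstrap resamples")
  per_cluster <- jac_sum / used
  structure(list(per_cluster = per_cluster,
                 overall = min(per_cluster),
                 B = B, n_used = used, n_skipped = skipped),
            class = "stability_report")
}

recluster_resample <- function(X, D, idx, method, k, seed) {
  if (method == "kmeans") {
    kmeans_correlation(X[idx, , drop = FALSE], k, seed)
  } else {
    Db <- D[idx, idx]
    run_clustering(NULL, Db, method, k, seed)
  }
}

#' Filter stratifications by bootstrap stability
#'
#' Retains stratifications whose overall (minimum per-cluster) stability is
#' at or above the threshold; those strictly below are excluded. Raising the
#' threshold never adds members.
#'
#' @param stratifications list of `stratification`s with `stability` filled.
#' @param threshold stability threshold (default 0.85).
#' @return the retained (possibly empty) list.
#' @export
filter_robust <- function(stratifications, threshold = 0.85) {
  keep <- vapply(stratifications, function(s) {
    if (is.null(s$stability)) stop("stability not computed for ", combo_id(s))
    s$stability$overall >= threshold
  }, logical(1))
  stratifications[keep]
}

#' Pair-counting Jaccard distance between two partitions
#'
#' Over all unordered patient pairs, with `n11` pairs co-clustered in both
#' partitions and `n10`/`n01` co-clustered in exactly one, the distance is
#' `1 - n11 / (n11 + n10 + n01)`. Invariant to cluster relabeling.
#'
#' @param labels_a,labels_b label vectors over the same patients.
#' @return distance in `[0, 1]`.
#' @export
partition_jaccard_distance <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n11 <- sum(choose(tab, 2))
  na <- sum(choose(rowSums(tab), 2))
  nb <- sum(choose(colSums(tab), 2))
  denom <- na + nb - n11   # n11 + n10 + n01
  if (denom == 0) return(0) # both all-singleton partitions: identical
  1 - n11 / denom
}

#' Group robust stratifications by partition distance
#'
#' Average-linkage hierarchical clustering of the stratifications under
#' pair-counting Jaccard distance, cut at height `tau`; groups with at least
#' `min_group_size` members qualify for a representative.
#'
#' @param stratifications list of `stratification`s (the robust set).
#' @param tau distance cut height (default 0.3).
#' @param min_group_size minimum qualifying group size (default 5).
#' @return list with `distance` (matrix), `membership` (group id per
#'   stratification), `groups` (list of index vectors) and `qualifies`
#'   (logical per group).
#' @export
group_stratifications <- function(stratifications, tau = 0.3,
                                  min_group_size = 5) {
  nS <- length(stratifications)
  if (nS == 0)
    return(list(distance = matrix(0, 0, 0), membership = integer(),
                groups = list(), qualifies = logical()))
  Dm <- matrix(0, nS, nS)
  if (nS > 1) {
    for (i in seq_len(nS - 1)) for (j in seq((i + 1), nS)) {
      d <- partition_jaccard_distance(stratifications[[i]]$labels,
                                      stratifications[[j]]$labels)
      Dm[i, j] <- d; Dm[j, i] <- d
    }
    tree <- stats::hclust(fast_dist(Dm), method = "average")
    memb <- stats::cutree(tree, h = tau)
  } else {
    memb <- 1L
  }
  groups <- split(seq_len(nS), memb)
  list(distance = Dm, membership = memb, groups = groups,
       qualifies = vapply(groups, length, integer(1)) >= min_group_size)
}

#' Centroid representative of a stratification group
#'
#' The member minimizing the sum of pair-counting Jaccard distances to all
#' other group members; ties go to the earliest member in combination order
#' (depth, then metric, then method — the construction order).
#'
#' @param group integer indices of the group members.
#' @param distance pairwise distance matrix over all stratifications.
#' @return the index (within `group`'s reference frame) of the centroid.
#' @export
select_centroid <- function(group, distance) {
  stopifnot(length(group) >= 1)
  sums <- rowSums(distance[group, group, drop = FALSE])
  group[which.min(sums)]
}
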
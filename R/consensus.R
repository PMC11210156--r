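# Consensus across imputations: modal k, patient co-assignment matrix and
# consolidation into one stratification per combination.

#' Modal number of clusters across imputations
#'
#' @param per_imputation_k integer vector of selected k values (each in
#'   `2..6`).
#' @return most frequent k; ties broken toward the smaller k.
#' @export
modal_k <- function(per_imputation_k) {
  stopifnot(length(per_imputation_k) >= 1,
            all(per_imputation_k %in% 2:6))
  tab <- table(per_imputation_k)
  as.integer(names(tab)[which.max(tab)])  # table names sorted ascending
}

#' Patient co-assignment frequencies across imputations
#'
#' `freq[i, j]` is the fraction of imputations in which patients i and j are
#' assigned to the same cluster; the complementary dissimilarity is
#' `D_mat = 1 - freq`. The diagonal is 1 by construction.
#'
#' @param label_sets list of label vectors over the same patients, one per
#'   imputation.
#' @return a `coassignment`: list with `freq`, `D_mat` and `M`.
#' @export
coassignment <- function(label_sets) {
  stopifnot(length(label_sets) >= 1)
  n <- length(label_sets[[1]])
  if (!all(lengths(label_sets) == n))
    stop("inconsistent patient sets across imputations")
  M <- length(label_sets)
  freq <- matrix(0, n, n)
  for (l in label_sets) {
    li <- as.integer(factor(l))
    Z <- matrix(0, n, max(li))
    Z[cbind(seq_len(n), li)] <- 1
    freq <- freq + tcrossprod(Z)   # 0/1 co-clustering indicator
  }
  freq <- freq / M
  structure(list(freq = freq, D_mat = 1 - freq, M = M),
            class = "coassignment")
}

#' Consolidate per-imputation clusterings into one stratification
#'
#' Rows of the co-assignment frequency matrix are treated as patient
#' profiles; correlation-based distance between profiles is clustered by
#' average-linkage hierarchical clustering and cut at `k`. With a single
#' imputation the input is a 0/1 block matrix and the original partition is
#' recovered (up to relabeling).
#'
#' @param coassign a [coassignment()].
#' @param k number of clusters (from [modal_k()]).
#' @return integer label vector.
#' @export
consolidate_stratification <- function(coassign, k) {
  stopifnot(inherits(coassign, "coassignment"), k >= 2)
  freq <- coassign$freq
  rsd <- apply(freq, 1, stats::sd)
  if (any(rsd == 0))
    stop("constant co-assignment profile for patient(s): ",
         paste(which(rsd == 0), collapse = ", "))
  D <- correlation_distance(freq)
  as.integer(stats::cutree(avg_linkage_tree(D), k = k))
}

#' Stratify every combination across depths and imputations
#'
#' For each depth the four combinations (correlation x \{hierarchical,
#' k-means\}, Gower x \{hierarchical, PAM\}) are clustered in every imputed
#' embedding over the whole k grid; per imputation the k is chosen by
#' validity-index consensus, the modal k is taken across imputations, and the
#' per-imputation labels at the modal k are consolidated through the
#' co-assignment matrix. The number of candidate stratifications is always
#' `4 * length(depths)`.
#'
#' @param embeddings nested list from [embed_all()]
#'   (`embeddings[[depth]][[imputation]]`).
#' @param k_grid candidate cluster numbers (subset of `2..6`).
#' @param seed integer seed for k-means seeding.
#' @param log optional run log.
#' @return list of `stratification` objects: `labels`, `depth_id`, `metric`,
#'   `method`, `k`, `per_imputation_k`, `imputation = "consensus"`.
#' @export
stratify_all <- function(embeddings, k_grid = 2:6, seed = 1, log = NULL) {
  stopifnot(all(k_grid %in% 2:6), length(k_grid) >= 1)
  grid <- combination_grid()
  out <- list()
  for (di in seq_along(embeddings)) {
    embs <- embeddings[[di]]
    m <- length(embs)
    depth_id <- embs[[1]]$depth_id
    seeds <- derive_seeds(seed, m, stream = 100L + di)
    # labels[[combo]][[imp]][[k index]], sel_k[combo, imp]
    labels <- rep(list(vector("list", m)), nrow(grid))
    sel_k <- matrix(NA_integer_, nrow(grid), m)
    for (ii in seq_len(m)) {
      X <- embs[[ii]]$matrix
      D_cor <- correlation_distance(X)
      D_gow <- gower_distance(X)
      for (ci in seq_len(nrow(grid))) {
        D <- if (grid$metric[ci] == "correlation") D_cor else D_gow
        labs <- cluster_grid(X, D, grid$method[ci], k_grid, seeds[ii] + ci)
        prof <- data.frame(k = k_grid, t(vapply(labs, function(l)
          validity_indices(D, l), numeric(3))))
        names(prof) <- c("k", "wb_ratio", "dunn", "avg_silhouette")
        sel_k[ci, ii] <- select_k_consensus(prof)
        labels[[ci]][[ii]] <- labs
      }
    }
    for (ci in seq_len(nrow(grid))) {
      k_star <- modal_k(sel_k[ci, ])
      ki <- match(k_star, k_grid)
      per_imp <- lapply(labels[[ci]], `[[`, ki)
      lab <- if (m == 1) per_imp[[1]]
             else consolidate_stratification(coassignment(per_imp), k_star)
      out[[length(out) + 1L]] <- structure(
        list(labels = lab, depth_id = depth_id,
             metric = grid$metric[ci], method = grid$method[ci],
             k = k_star, per_imputation_k = sel_k[ci, ],
             imputation = "consensus", stability = NULL),
        class = "stratification")
    }
    log_msg(log, "depth ", depth_id, ": 4 candidate stratifications (k = ",
            paste(vapply(out[(length(out) - 3):length(out)], `[[`,
                         numeric(1), "k"), collapse = ","), ")")
  }
  out
}

#' @export
print.stratification <- function(x, ...) {
  cat("stratification ", combo_id(x), ": k=", x$k, ", sizes [",
      paste(table(x$labels), collapse = ", "), "]", sep = "")
  if (!is.null(x$stability))
    cat(", min stability ", sprintf("%.3f", x$stability$overall), sep = "")
  cat("\n")
  invisible(x)
}
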
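# Data complexity reduction: feature dendrogram, depth enumeration and
# per-depth principal-component embeddings.
#
# The dendrogram is computed once, on the pre-imputation encoded matrix
# (pairwise-complete correlations), and shared across all imputations.

#' Build the feature dendrogram
#'
#' Agglomerates encoded columns with dissimilarity `1 - |r|` (Pearson, on
#' pairwise-complete observations; collinearity is sign-agnostic) and average
#' linkage by default. Perfectly collinear columns merge at height 0;
#' independent columns merge near height 1.
#'
#' @param encoded an `encoded_matrix` (missing values allowed).
#' @param feature_distance `"abs_cor"` (`1 - |r|`, default) or `"cor"`
#'   (`1 - r`).
#' @param linkage linkage for [stats::hclust()] (default `"average"`).
#' @return a `feature_dendrogram`: list with the `hclust` tree, the column
#'   dissimilarity matrix and the distance tag.
#' @export
build_feature_dendrogram <- function(encoded,
                                     feature_distance = c("abs_cor", "cor"),
                                     linkage = "average") {
  feature_distance <- match.arg(feature_distance)
  mat <- if (inherits(encoded, "encoded_matrix")) encoded$matrix else encoded
  d <- ncol(mat)
  if (d < 2) stop("at least 2 encoded columns required")
  sds <- apply(mat, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0))
    stop("constant column(s) (undefined correlation): ",
         paste(colnames(mat)[is.na(sds) | sds == 0], collapse = ", "))
  obs <- !is.na(mat)
  joint <- crossprod(obs)
  if (any(joint < 3)) {
    bad <- which(joint < 3, arr.ind = TRUE)[1, ]
    stop("columns '", colnames(mat)[bad[1]], "' and '", colnames(mat)[bad[2]],
         "' share fewer than 3 jointly observed rows")
  }
  r <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  dm <- if (feature_distance == "abs_cor") 1 - abs(r) else 1 - r
  dm[dm < 0] <- 0  # numerical noise
  diag(dm) <- 0
  tree <- stats::hclust(fast_dist(dm), method = linkage)
  structure(list(tree = tree, distance_matrix = dm,
                 feature_distance = feature_distance, linkage = linkage,
                 columns = colnames(mat)),
            class = "feature_dendrogram")
}

#' Enumerate the depths of a feature dendrogram
#'
#' Cutting the tree immediately below each distinct merge height yields one
#' grouping of columns per cut; the trivial partitions (everything in one
#' group, everything a singleton) are excluded, so a tree over `d` columns
#' with all-distinct merge heights yields exactly `d - 2` depths, with group
#' counts `2 .. d-1`. Tied merge heights collapse to a single depth.
#'
#' @param dendrogram a [build_feature_dendrogram()] result.
#' @return list of `depth_partition`s, each with `depth_id`, `groups`
#'   (list of column-name vectors) and `n_groups`, ordered from coarsest
#'   (2 groups) to finest.
#' @export
enumerate_depths <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "feature_dendrogram"))
  tree <- dendrogram$tree
  d <- length(dendrogram$columns)
  if (d < 3) stop("no non-trivial depth exists for fewer than 3 columns")
  heights <- sort(unique(tree$height), decreasing = TRUE)
  parts <- list()
  seen <- character()
  for (h in heights) {
    memb <- stats::cutree(tree, h = h)
    g <- max(memb)
    if (g < 2 || g > d - 1) next
    key <- paste(memb, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    parts[[length(parts) + 1L]] <- memb
  }
  lapply(seq_along(parts), function(i) {
    memb <- parts[[i]]
    structure(list(depth_id = i,
                   groups = split(dendrogram$columns, memb),
                   n_groups = max(memb)),
              class = "depth_partition")
  })
}

#' Embed one complete dataset at one depth
#'
#' Within each multi-column group, columns are standardized (mean 0, SD 1)
#' and replaced by their first principal components: at most 3, never more
#' than the group rank, zero-variance components dropped. Singleton groups
#' pass through as the standardized column. Components are concatenated in
#' group order.
#'
#' @param complete a complete numeric matrix (one imputed dataset) whose
#'   columns cover the depth's groups.
#' @param depth a `depth_partition`.
#' @param max_components per-group component cap (default 3).
#' @return an `embedding`: list with numeric `matrix` (patients x
#'   components, no missing values) and `provenance` (component, group,
#'   source: PC rank or passthrough column).
#' @export
embed_depth <- function(complete, depth, max_components = 3) {
  stopifnot(inherits(depth, "depth_partition"))
  mat <- if (inherits(complete, "encoded_matrix")) complete$matrix else complete
  if (anyNA(mat)) stop("embed_depth requires a complete matrix")
  pieces <- list(); prov <- list()
  for (gi in seq_along(depth$groups)) {
    cols <- depth$groups[[gi]]
    sub <- mat[, cols, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (all(sds == 0))
      stop("group ", gi, " (", paste(cols, collapse = ", "),
           ") has zero total variance")
    # zero-variance columns standardize to 0 and carry no signal
    sub <- sweep(sub, 2, colMeans(sub))
    sub <- sweep(sub, 2, ifelse(sds > 0, sds, 1), "/")
    if (length(cols) == 1) {
      nm <- paste0("G", gi, ".", cols)
      pieces[[nm]] <- drop(sub)
      prov[[length(prov) + 1L]] <- data.frame(component = nm, group = gi,
                                              source = cols, pc_rank = NA)
    } else {
      pca <- stats::prcomp(sub, center = FALSE, scale. = FALSE)
      keep <- which(pca$sdev > 1e-8)
      keep <- keep[seq_len(min(length(keep), max_components, length(cols)))]
      for (r in keep) {
        nm <- paste0("G", gi, ".PC", r)
        pieces[[nm]] <- pca$x[, r]
        prov[[length(prov) + 1L]] <- data.frame(component = nm, group = gi,
                                                source = "PCA", pc_rank = r)
      }
    }
  }
  emb <- do.call(cbind, pieces)
  rownames(emb) <- rownames(mat)
  structure(list(matrix = emb, depth_id = depth$depth_id,
                 provenance = do.call(rbind, prov)),
            class = "embedding")
}

#' Embeddings for every depth and imputation
#'
#' Applies [embed_depth()] to each imputed dataset at each depth. The number
#' of embeddings equals `length(depths) * imputations$m`.
#'
#' @param imputations an `imputation_set`.
#' @param depths list of `depth_partition`s.
#' @return nested list: `result[[depth]][[imputation]]` is an `embedding`.
#' @export
embed_all <- function(imputations, depths) {
  stopifnot(inherits(imputations, "imputation_set"))
  lapply(depths, function(dp)
    lapply(imputations$datasets, embed_depth, depth = dp))
}
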
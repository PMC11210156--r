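# Orchestration: configuration, full run and reporting.

#' Pipeline configuration
#'
#' Desk-scale defaults (`m = 20`, `B = 100`) keep a full run tractable on a
#' laptop; the framework's reference settings for a full cohort analysis are
#' `m = 1000` imputations and `B = 1000` bootstraps with the same threshold
#' (0.85), k grid (2..6) and minimum group size (5).
#'
#' @param m number of imputations.
#' @param B number of bootstrap resamples per candidate stratification.
#' @param k_grid candidate cluster counts (subset of `2..6`).
#' @param stability_threshold bootstrap-stability exclusion threshold.
#' @param tau cut height for grouping stratifications by partition distance.
#' @param min_group_size minimum members for a group to yield a
#'   representative.
#' @param max_missing_frac per-feature missingness filter (strict).
#' @param n_cycles chained-equation cycles per imputation.
#' @param feature_distance,linkage dendrogram options
#'   (see [build_feature_dendrogram()]).
#' @param depth_subset optional integer vector restricting which depths are
#'   stratified (useful when the number of variables is large).
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param verbose echo log lines as messages.
#' @return a `run_config` list.
#' @export
run_config <- function(m = 20, B = 100, k_grid = 2:6,
                       stability_threshold = 0.85, tau = 0.3,
                       min_group_size = 5, max_missing_frac = 0.30,
                       n_cycles = 5, feature_distance = "abs_cor",
                       linkage = "average", depth_subset = NULL,
                       seed = 1, verbose = FALSE) {
  stopifnot(m >= 1, B >= 1, all(k_grid %in% 2:6),
            stability_threshold > 0, stability_threshold <= 1,
            tau >= 0, min_group_size >= 1)
  structure(list(m = m, B = B, k_grid = sort(unique(as.integer(k_grid))),
                 stability_threshold = stability_threshold, tau = tau,
                 min_group_size = min_group_size,
                 max_missing_frac = max_missing_frac, n_cycles = n_cycles,
                 feature_distance = feature_distance, linkage = linkage,
                 depth_subset = depth_subset, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

#' Run the full stratification pipeline
#'
#' Executes: missingness filter, one-hot encoding, feature dendrogram on the
#' pre-imputation matrix, depth enumeration, chained-equations imputation,
#' per-depth embeddings, per-combination stratification with modal-k
#' consensus across imputations, bootstrap stability, the robustness filter,
#' pair-counting partition distances, grouping and centroid selection. The
#' run completes normally whether the outcome is none, one or several robust
#' stratifications.
#'
#' @param cohort a [cohort_table()] (use [read_cohort()] for files).
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, [write_outputs()] is
#'   called.
#' @return a `strat_ensemble`: `candidates` (all stratifications, stability
#'   filled), `robust`, `distance`, `groups`, `membership`,
#'   `representatives`, `depths`, `patient_ids`, `config`, `log`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "run_config"))
  log <- new_log(config$verbose)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("missingness filter",
    filter_features_by_missingness(cohort, config$max_missing_frac, log))
  encoded <- stage("encoding", encode_cohort(cohort))
  log_msg(log, "encoded ", ncol(encoded$matrix), " columns from ",
          ncol(cohort$data), " features, ", length(cohort$patient_ids),
          " patients")

  dendro <- stage("feature dendrogram",
    build_feature_dendrogram(encoded, config$feature_distance, config$linkage))
  depths <- stage("depth enumeration", enumerate_depths(dendro))
  if (!is.null(config$depth_subset))
    depths <- depths[intersect(config$depth_subset, seq_along(depths))]
  log_msg(log, length(depths), " depths enumerated")

  m_eff <- if (any(cohort$missing_mask)) config$m else 1L
  if (m_eff != config$m)
    log_msg(log, "complete data: single imputation path (m = 1)")
  imps <- stage("imputation",
    impute_chained(encoded, m = m_eff, seed = derive_seeds(config$seed, 1, 1L),
                   n_cycles = config$n_cycles, log = log))
  embeddings <- stage("embedding", embed_all(imps, depths))
  log_msg(log, length(depths) * m_eff, " embeddings materialized (",
          length(depths), " depths x m = ", m_eff, ")")

  candidates <- stage("stratification",
    stratify_all(embeddings, config$k_grid,
                 seed = derive_seeds(config$seed, 1, 2L), log = log))
  log_msg(log, length(candidates), " candidate stratifications")

  boot_seeds <- derive_seeds(config$seed, length(candidates), 3L)
  candidates <- stage("bootstrap stability", {
    depth_ids <- vapply(depths, `[[`, integer(1), "depth_id")
    ref_dist <- list()  # per-depth distance matrices, computed on demand
    for (i in seq_along(candidates)) {
      s <- candidates[[i]]
      di <- match(s$depth_id, depth_ids)
      ref_emb <- embeddings[[di]][[1]]  # reference imputation path
      key <- paste0(di, "_", s$metric)
      if (s$method != "kmeans" && is.null(ref_dist[[key]]))
        ref_dist[[key]] <- patient_distance(ref_emb$matrix, s$metric)
      candidates[[i]]$stability <- bootstrap_stability(
        ref_emb, s$labels, s$metric, s$method, s$k,
        B = config$B, seed = boot_seeds[i],
        distance = ref_dist[[key]], log = log)
    }
    candidates
  })

  robust <- stage("robustness filter",
    filter_robust(candidates, config$stability_threshold))
  log_msg(log, length(robust), " robust stratifications (threshold ",
          config$stability_threshold, ")")

  grouping <- stage("grouping",
    group_stratifications(robust, config$tau, config$min_group_size))
  rep_idx <- unlist(lapply(grouping$groups[grouping$qualifies],
                           select_centroid, distance = grouping$distance))
  representatives <- robust[rep_idx]
  log_msg(log, length(grouping$groups), " groups, ",
          length(representatives), " representatives",
          if (length(representatives) == 0) " (no robust stratification)"
          else "")

  ensemble <- structure(list(
    candidates = candidates, robust = robust,
    distance = grouping$distance, membership = grouping$membership,
    groups = grouping$groups, qualifies = grouping$qualifies,
    representatives = representatives,
    n_depths = length(depths), m = m_eff,
    patient_ids = cohort$patient_ids, config = config,
    log = log$lines), class = "strat_ensemble")

  if (!is.null(out_dir))
    write_outputs(out_dir, ensemble,
                  summary = list(m = m_eff, B = config$B,
                                 n_depths = length(depths),
                                 seed = config$seed),
                  log_lines = log$lines)
  ensemble
}

#' @export
print.strat_ensemble <- function(x, ...) {
  cat("strat_ensemble: ", length(x$candidates), " candidates -> ",
      length(x$robust), " robust -> ", length(x$representatives),
      " representatives\n", sep = "")
  for (s in x$representatives) print(s)
  if (length(x$representatives) == 0)
    cat("  no robust stratification\n")
  invisible(x)
}

#' Summarize a completed run
#'
#' @param ensemble a `strat_ensemble` from [run_pipeline()].
#' @return data.frame with one row per candidate: combination, k, cluster
#'   sizes, overall stability, robustness flag, group membership and
#'   representative flag. Printed with a header mirroring the count
#'   narrative (candidates, robust, groups, representatives).
#' @export
report_run <- function(ensemble) {
  stopifnot(inherits(ensemble, "strat_ensemble"))
  robust_ids <- vapply(ensemble$robust, combo_id, character(1))
  rep_ids <- vapply(ensemble$representatives, combo_id, character(1))
  rows <- lapply(ensemble$candidates, function(s) {
    id <- combo_id(s)
    data.frame(stratification = id, depth_id = s$depth_id,
               metric = s$metric, method = s$method, k = s$k,
               sizes = paste(table(s$labels), collapse = "/"),
               min_stability = s$stability$overall %||% NA_real_,
               robust = id %in% robust_ids,
               group = if (id %in% robust_ids)
                 ensemble$membership[match(id, robust_ids)] else NA_integer_,
               representative = id %in% rep_ids)
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- c(candidates = length(ensemble$candidates),
                           robust = length(ensemble$robust),
                           groups = length(ensemble$groups),
                           representatives = length(ensemble$representatives))
  out
}
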
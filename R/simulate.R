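# Synthetic mixed-type cohorts with planted subgroups, correlated feature
# blocks and controlled missingness. Categorical features are obtained by
# thresholding latent Gaussians so block correlation survives across kinds.

#' Simulation configuration
#'
#' Describes a synthetic cohort: correlated feature blocks of mixed kinds,
#' planted patient subgroups with a controlled effect size, and a missingness
#' mechanism. The defaults emulate a hospital-admission clinical panel:
#' 766 patients, 74 features in three correlated blocks (a numeric-heavy
#' laboratory block, a mixed clinical-manifestation block and a small
#' demographics block), three planted subgroups of moderate separation and
#' 15% MCAR missingness.
#'
#' @param n_patients number of patients (must be at least `5 * n_clusters`).
#' @param feature_blocks list of blocks, each a list with `kinds` (named
#'   counts over `numeric`, `binary`, `nominal`, `ordinal`) and `rho`
#'   (exchangeable within-block latent correlation in `[0, 1)`).
#' @param n_clusters number of planted subgroups (>= 1).
#' @param effect_size standardized separation delta (>= 0) between subgroup
#'   means on informative features, in within-cluster SD units.
#' @param informative_frac proportion of features carrying subgroup signal.
#' @param missing_rate overall missingness proportion in `[0, 0.5)`.
#' @param missing_mechanism `"MCAR"` or `"MAR"`.
#' @param nominal_levels,ordinal_levels number of category levels generated
#'   for nominal / ordinal features.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 766,
                       feature_blocks = list(
                         list(kinds = c(numeric = 20, binary = 6,
                                        nominal = 2, ordinal = 2), rho = 0.45),
                         list(kinds = c(numeric = 12, binary = 10,
                                        nominal = 2, ordinal = 2), rho = 0.30),
                         list(kinds = c(numeric = 8, binary = 8,
                                        nominal = 1, ordinal = 1), rho = 0.15)),
                       n_clusters = 3,
                       effect_size = 1.5,
                       informative_frac = 0.4,
                       missing_rate = 0.15,
                       missing_mechanism = c("MCAR", "MAR"),
                       nominal_levels = 3,
                       ordinal_levels = 4,
                       seed = 1) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_clusters >= 1, effect_size >= 0,
            informative_frac >= 0, informative_frac <= 1,
            missing_rate >= 0, missing_rate < 0.5,
            nominal_levels >= 2, ordinal_levels >= 2)
  if (n_patients < 5 * n_clusters)
    stop("n_patients must be >= 5 * n_clusters")
  for (b in feature_blocks) {
    if (is.null(b$kinds) || sum(b$kinds) < 1) stop("each block needs features")
    if (b$rho < 0 || b$rho >= 1)
      stop("infeasible block correlation rho=", b$rho,
           " (must be in [0,1) for a positive-definite block)")
  }
  structure(list(n_patients = n_patients, feature_blocks = feature_blocks,
                 n_clusters = n_clusters, effect_size = effect_size,
                 informative_frac = informative_frac,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 nominal_levels = nominal_levels,
                 ordinal_levels = ordinal_levels,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic mixed-type cohort with planted subgroups
#'
#' Patients are assigned to `n_clusters` subgroups; each feature block draws
#' latent Gaussians with exchangeable correlation `rho`, informative features
#' receive a subgroup mean shift of `effect_size` within-cluster SDs
#' (subgroups take turns being the shifted one, round-robin across
#' informative features, so every pair of subgroups is separated by delta on
#' a subset of features). Numeric features are affine transforms of the
#' latent variable; binary/nominal/ordinal features are produced by
#' thresholding the latent variable at empirical quantiles. Missingness is
#' injected afterwards via [inject_missingness()].
#'
#' @param config a [sim_config()].
#' @return a `simulated_cohort`: list with `cohort` (a [cohort_table()]),
#'   `true_labels` (integer vector) and `generator_log` (realized
#'   parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  k <- config$n_clusters

  # balanced subgroup assignment, every subgroup non-empty by construction
  labels <- sample(rep_len(seq_len(k), n))

  blocks <- config$feature_blocks
  kinds_all <- unlist(lapply(blocks, function(b)
    rep(names(b$kinds), b$kinds)), use.names = FALSE)
  p <- length(kinds_all)
  n_inf <- round(config$informative_frac * p)
  informative <- sort(sample.int(p, n_inf))
  # round-robin: informative feature j lifts one subgroup by delta
  lifted <- ((seq_along(informative) - 1L) %% k) + 1L

  latent <- matrix(0, n, p)
  col0 <- 0L
  for (b in blocks) {
    pb <- sum(b$kinds)
    sigma <- matrix(b$rho, pb, pb); diag(sigma) <- 1
    z <- matrix(stats::rnorm(n * pb), n, pb) %*% chol(sigma)
    latent[, col0 + seq_len(pb)] <- z
    col0 <- col0 + pb
  }
  mu <- matrix(0, k, p)
  mu[cbind(lifted, informative)] <- config$effect_size
  latent <- latent + mu[labels, , drop = FALSE]

  feats <- vector("list", p)
  schema <- vector("list", p)
  counters <- c(numeric = 0L, binary = 0L, nominal = 0L, ordinal = 0L)
  lv_pool <- LETTERS
  for (j in seq_len(p)) {
    kind <- kinds_all[j]
    counters[kind] <- counters[kind] + 1L
    nm <- paste0(substr(kind, 1, 3), counters[kind])
    z <- latent[, j]
    if (kind == "numeric") {
      scale_j <- stats::runif(1, 0.5, 3)
      shift_j <- stats::runif(1, -2, 5)
      feats[[j]] <- shift_j + scale_j * z
      schema[[j]] <- list(name = nm, kind = "numeric")
    } else if (kind == "binary") {
      prev <- stats::runif(1, 0.25, 0.75)
      cut <- stats::quantile(z, prev, names = FALSE)
      feats[[j]] <- c("no", "yes")[(z > cut) + 1L]
      schema[[j]] <- list(name = nm, kind = "binary", levels = c("no", "yes"))
    } else {
      L <- if (kind == "nominal") config$nominal_levels else config$ordinal_levels
      cuts <- stats::quantile(z, seq_len(L - 1) / L, names = FALSE)
      idx <- findInterval(z, cuts) + 1L
      lv <- if (kind == "nominal") lv_pool[seq_len(L)]
            else paste0("grade", seq_len(L))
      feats[[j]] <- lv[idx]
      schema[[j]] <- list(name = nm, kind = kind, levels = lv)
    }
    names(feats)[j] <- nm
  }
  df <- as.data.frame(feats, check.names = FALSE, optional = TRUE)
  cohort <- cohort_table(df, feature_schema(schema))

  if (config$missing_rate > 0) {
    cohort <- inject_missingness(cohort, config$missing_mechanism,
                                 config$missing_rate,
                                 seed = derive_seeds(config$seed, 1, 7L))
  }
  structure(list(cohort = cohort,
                 true_labels = labels,
                 generator_log = list(
                   n_features = p, informative = informative,
                   lifted_cluster = lifted,
                   effect_size = config$effect_size,
                   config = config)),
            class = "simulated_cohort")
}

#' Inject missing values into a cohort table
#'
#' Under MCAR each cell is independently missing with probability `rate`.
#' Under MAR, the first fully observed numeric column is kept complete as an
#' anchor and the missingness probability of every other cell follows a
#' logistic model in the standardized anchor value, with the intercept
#' calibrated so the expected overall missing fraction equals `rate`.
#'
#' @param cohort a [cohort_table()].
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate proportion in `[0, 0.5)`.
#' @param seed integer seed.
#' @param mar_slope logistic slope on the standardized anchor (MAR only).
#' @param enforce_filter if `TRUE`, error when `rate` is incompatible with
#'   the strict 30% per-feature missingness filter.
#' @return the `cohort_table` with updated cells and missingness mask.
#' @export
inject_missingness <- function(cohort, mechanism = c("MCAR", "MAR"),
                               rate, seed = 1, mar_slope = 1.5,
                               enforce_filter = FALSE) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(cohort, "cohort_table"), rate >= 0, rate < 0.5)
  if (enforce_filter && rate >= 0.30)
    stop("rate ", rate, " would violate the <30% per-feature missingness filter")
  if (rate == 0) return(cohort)
  set.seed(seed)
  df <- cohort$data
  n <- nrow(df); p <- ncol(df)
  if (mechanism == "MCAR") {
    mask <- matrix(stats::runif(n * p) < rate, n, p)
  } else {
    kinds <- schema_kinds(cohort$schema)[names(df)]
    complete_num <- which(kinds == "numeric" &
                          colSums(is.na(as.matrix(df))) == 0)
    if (!length(complete_num))
      stop("MAR requires at least one fully observed numeric anchor column")
    anchor <- complete_num[1]
    z <- as.numeric(scale(df[[anchor]]))
    # calibrate intercept so mean missingness over non-anchor cells = rate
    target <- rate * p / (p - 1)
    if (target >= 1) stop("MAR rate infeasible for ", p, " features")
    a <- stats::uniroot(function(a) mean(stats::plogis(a + mar_slope * z)) - target,
                        c(-20, 20))$root
    pr <- stats::plogis(a + mar_slope * z)
    mask <- matrix(stats::runif(n * p) < pr, n, p)  # recycles pr down columns
    mask[, anchor] <- FALSE
  }
  for (j in seq_len(p)) df[[j]][mask[, j]] <- NA
  cohort_table(df, cohort$schema, cohort$patient_ids)
}

#' Write a simulated cohort to disk
#'
#' Writes the cohort CSV, its schema (YAML) and the planted labels CSV; the
#' on-disk form round-trips through [read_cohort()].
#'
#' @param sim a `simulated_cohort` from [generate_cohort()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_simulated_cohort <- function(sim, dir, prefix = "cohort") {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cbind(patient_id = sim$cohort$patient_ids, sim$cohort$data)
  table_path <- file.path(dir, paste0(prefix, ".csv"))
  utils::write.csv(tab, table_path, row.names = FALSE, na = "")
  schema_path <- file.path(dir, paste0(prefix, "_schema.yaml"))
  write_schema(sim$cohort$schema, schema_path)
  labels_path <- file.path(dir, paste0(prefix, "_true_labels.csv"))
  utils::write.csv(data.frame(patient_id = sim$cohort$patient_ids,
                              true_label = sim$true_labels),
                   labels_path, row.names = FALSE)
  invisible(c(table = table_path, schema = schema_path, labels = labels_path))
}
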
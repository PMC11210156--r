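# Cohort input: typed tables, schemas, missingness filter, one-hot encoding.

#' Construct a feature schema
#'
#' A schema declares, for every column of a cohort table, its measurement
#' kind: `numeric`, `binary`, `nominal` (unordered categories) or `ordinal`
#' (categories in rank order). Nominal and ordinal features must declare at
#' least two levels; ordinal levels are interpreted as being in increasing
#' rank order. Binary features may declare their two level codes (first level
#' encodes as 0, second as 1); if omitted, `"0"`/`"1"` is assumed.
#'
#' @param features list of entries, each a list with `name`, `kind` and
#'   (for categorical kinds) `levels`.
#' @return an object of class `feature_schema`.
#' @export
feature_schema <- function(features) {
  stopifnot(is.list(features), length(features) >= 1)
  kinds <- c("numeric", "binary", "nominal", "ordinal")
  feats <- lapply(features, function(f) {
    if (is.null(f$name) || is.null(f$kind))
      stop("schema entries need 'name' and 'kind'")
    f$kind <- match.arg(f$kind, kinds)
    if (f$kind %in% c("nominal", "ordinal")) {
      if (length(f$levels) < 2)
        stop("feature '", f$name, "': ", f$kind, " kind requires >=2 levels")
      f$levels <- as.character(f$levels)
      if (anyDuplicated(f$levels))
        stop("feature '", f$name, "': duplicated levels")
    } else if (f$kind == "binary") {
      if (is.null(f$levels)) f$levels <- c("0", "1")
      f$levels <- as.character(f$levels)
      if (length(f$levels) != 2)
        stop("feature '", f$name, "': binary kind requires exactly 2 levels")
    } else {
      f$levels <- NULL
    }
    f[c("name", "kind", "levels")]
  })
  nms <- vapply(feats, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate feature names in schema")
  names(feats) <- nms
  structure(feats, class = "feature_schema")
}

#' Read a feature schema from a YAML or JSON file
#'
#' The file holds a list of records with fields `name`, `kind` and optional
#' `levels` (see [feature_schema()]).
#'
#' @param path file path; format chosen by extension (`.json` vs YAML).
#' @return a `feature_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  # allow either a bare list of entries or a top-level `features:` key
  if (!is.null(raw$features)) raw <- raw$features
  feature_schema(raw)
}

#' Write a feature schema to YAML
#' @param schema a `feature_schema`.
#' @param path output file path.
#' @export
write_schema <- function(schema, path) {
  entries <- lapply(unclass(schema), function(f) {
    out <- list(name = f$name, kind = f$kind)
    if (!is.null(f$levels)) out$levels <- as.list(f$levels)
    out
  })
  yaml::write_yaml(list(features = unname(entries)), path)
  invisible(path)
}

schema_kinds <- function(schema) {
  vapply(unclass(schema), `[[`, character(1), "kind")
}

# Validate one column of raw character data against its schema entry.
# Returns the typed column (numeric or character); errors name the column.
validate_column <- function(x, feat) {
  obs <- !is.na(x)
  if (feat$kind == "numeric") {
    suppressWarnings(num <- as.numeric(x))
    bad <- obs & is.na(num)
    if (any(bad))
      stop("column '", feat$name, "': non-numeric value '", x[which(bad)[1]],
           "' in a numeric feature")
    return(num)
  }
  bad <- obs & !(x %in% feat$levels)
  if (any(bad))
    stop("column '", feat$name, "': value '", x[which(bad)[1]],
         "' outside declared levels (", paste(feat$levels, collapse = ", "), ")")
  x
}

#' Construct a cohort table from a typed data frame
#'
#' @param data data.frame of feature columns (numeric or character), possibly
#'   with `NA` cells.
#' @param schema a [feature_schema()] covering every column of `data`.
#' @param patient_ids unique row identifiers (default `P1..Pn`).
#' @return an object of class `cohort_table` with elements `data`,
#'   `schema`, `patient_ids` and logical `missing_mask`.
#' @export
cohort_table <- function(data, schema, patient_ids = NULL) {
  stopifnot(is.data.frame(data), inherits(schema, "feature_schema"))
  missing_sch <- setdiff(names(data), names(schema))
  if (length(missing_sch))
    stop("schema does not cover column(s): ", paste(missing_sch, collapse = ", "))
  data <- data[, intersect(names(schema), names(data)), drop = FALSE]
  if (ncol(data) < 2) stop("a cohort requires at least 2 features")
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(nrow(data)))
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids))
    stop("duplicate patient id: ", patient_ids[which(duplicated(patient_ids))[1]])
  for (nm in names(data)) {
    x <- data[[nm]]
    if (!is.numeric(x)) x <- as.character(x)
    data[[nm]] <- validate_column(x, schema[[nm]])
  }
  mask <- is.na(as.matrix(data))
  dimnames(mask) <- list(patient_ids, names(data))
  rownames(data) <- NULL
  structure(list(data = data, schema = schema, patient_ids = patient_ids,
                 missing_mask = mask),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table: ", length(x$patient_ids), " patients x ",
      ncol(x$data), " features (",
      sprintf("%.1f%%", 100 * mean(x$missing_mask)), " missing)\n", sep = "")
  kinds <- table(schema_kinds(x$schema)[names(x$data)])
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a cohort table and schema from disk
#'
#' Reads a patient-by-feature CSV (header row; RFC 4180) together with a
#' schema file and validates every cell against its declared kind. Cells
#' equal to one of `na_tokens` (case-insensitive) or left empty are treated
#' as missing.
#'
#' @param table_path CSV file, one row per patient.
#' @param schema_path schema file for [read_schema()].
#' @param id_col name of the patient-identifier column in the CSV; if absent
#'   row numbers are used.
#' @param na_tokens character vector of missing-value tokens.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(table_path, schema_path, id_col = "patient_id",
                        na_tokens = c("", "NA", "NaN")) {
  if (!file.exists(table_path)) stop("cohort file not found: ", table_path)
  schema <- read_schema(schema_path)
  df <- utils::read.csv(table_path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  ids <- NULL
  if (id_col %in% names(df)) {
    ids <- df[[id_col]]
    df[[id_col]] <- NULL
  }
  unknown <- setdiff(names(df), names(schema))
  if (length(unknown))
    stop("unknown column(s) not in schema: ", paste(unknown, collapse = ", "))
  tok <- tolower(na_tokens)
  for (nm in names(df)) {
    x <- trimws(df[[nm]])
    x[tolower(x) %in% tok] <- NA_character_
    df[[nm]] <- x
  }
  cohort_table(df, schema, patient_ids = ids)
}

#' Drop features with too many missing values
#'
#' Retains exactly the features whose missing fraction is strictly below
#' `max_missing_frac`; a feature missing in 30 of 100 patients is dropped at
#' the default threshold of 0.30. The operation is idempotent.
#'
#' @param cohort a [cohort_table()].
#' @param max_missing_frac proportion in (0, 1].
#' @param log optional run log.
#' @return the filtered `cohort_table` (errors if fewer than 2 features
#'   survive).
#' @export
filter_features_by_missingness <- function(cohort, max_missing_frac = 0.30,
                                           log = NULL) {
  stopifnot(inherits(cohort, "cohort_table"),
            max_missing_frac > 0, max_missing_frac <= 1)
  frac <- colMeans(cohort$missing_mask)
  keep <- frac < max_missing_frac
  if (sum(keep) < 2)
    stop("fewer than 2 features have missingness < ", max_missing_frac)
  dropped <- names(frac)[!keep]
  if (length(dropped))
    log_msg(log, "missingness filter dropped: ",
            paste(sprintf("%s (%.1f%%)", dropped, 100 * frac[!keep]),
                  collapse = ", "))
  sch <- feature_schema(unclass(cohort$schema)[names(frac)[keep]])
  cohort_table(cohort$data[, keep, drop = FALSE], sch, cohort$patient_ids)
}

#' One-hot encode a cohort table
#'
#' Numeric features map to themselves; binary features to a single 0/1
#' column; ordinal features to a single 0-based integer rank; nominal
#' features with L levels to L indicator columns (named `feature=level`)
#' that sum to 1 where the source is observed. Missingness propagates: all
#' encoded columns of a missing cell are `NA`.
#'
#' @param cohort a [cohort_table()].
#' @return an object of class `encoded_matrix`: list with numeric `matrix`,
#'   `provenance` (data.frame mapping encoded column to source feature,
#'   kind and level), `patient_ids` and `schema`.
#' @export
encode_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  cols <- list(); prov <- list()
  for (nm in names(cohort$data)) {
    f <- cohort$schema[[nm]]
    x <- cohort$data[[nm]]
    if (f$kind == "numeric") {
      cols[[nm]] <- as.numeric(x)
      prov[[length(prov) + 1L]] <- data.frame(column = nm, feature = nm,
                                              kind = "numeric", level = NA)
    } else if (f$kind == "binary") {
      v <- match(x, f$levels) - 1
      cols[[nm]] <- as.numeric(v)
      prov[[length(prov) + 1L]] <- data.frame(column = nm, feature = nm,
                                              kind = "binary", level = NA)
    } else if (f$kind == "ordinal") {
      v <- match(x, f$levels) - 1
      cols[[nm]] <- as.numeric(v)
      prov[[length(prov) + 1L]] <- data.frame(column = nm, feature = nm,
                                              kind = "ordinal", level = NA)
    } else { # nominal -> one indicator column per level
      for (lv in f$levels) {
        cn <- paste0(nm, "=", lv)
        v <- as.numeric(x == lv)
        cols[[cn]] <- v
        prov[[length(prov) + 1L]] <- data.frame(column = cn, feature = nm,
                                                kind = "nominal", level = lv)
      }
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- cohort$patient_ids
  structure(list(matrix = mat,
                 provenance = do.call(rbind, prov),
                 patient_ids = cohort$patient_ids,
                 schema = cohort$schema),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("encoded_matrix: ", nrow(x$matrix), " patients x ", ncol(x$matrix),
      " encoded columns (", length(unique(x$provenance$feature)),
      " source features)\n", sep = "")
  invisible(x)
}

# Inverse of encode_cohort for a complete (or partially observed) encoded
# matrix: reconstructs the typed feature data frame. Used by the imputation
# engine and by round-trip tests.
decode_encoded <- function(mat, provenance, schema) {
  feats <- unique(provenance$feature)
  out <- vector("list", length(feats))
  names(out) <- feats
  for (nm in feats) {
    f <- schema[[nm]]
    pv <- provenance[provenance$feature == nm, , drop = FALSE]
    if (f$kind == "numeric") {
      out[[nm]] <- mat[, pv$column]
    } else if (f$kind %in% c("binary", "ordinal")) {
      lv <- if (f$kind == "binary") f$levels else f$levels
      out[[nm]] <- lv[round(mat[, pv$column]) + 1]
    } else {
      block <- mat[, pv$column, drop = FALSE]
      idx <- apply(block, 1, function(r) if (anyNA(r)) NA_integer_ else which.max(r))
      out[[nm]] <- pv$level[idx]
    }
  }
  as.data.frame(out, check.names = FALSE, optional = TRUE)
}

#' Write pipeline outputs to a run directory
#'
#' Writes `labels.csv` (patient id plus one column per representative
#' stratification), `stability.csv` (one row per candidate stratification and
#' cluster), a machine-readable `summary.json` (byte-identical across reruns
#' with the same inputs) and `log.txt`.
#'
#' @param run_dir output directory (created if needed).
#' @param ensemble a `strat_ensemble` from [run_pipeline()].
#' @param patient_ids patient identifiers (taken from the ensemble if
#'   omitted).
#' @param summary named list merged into the JSON summary.
#' @param log_lines character vector for `log.txt`.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(run_dir, ensemble, patient_ids = NULL,
                          summary = list(), log_lines = character()) {
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(run_dir)) stop("cannot create run directory: ", run_dir)
  patient_ids <- patient_ids %||% ensemble$patient_ids
  reps <- ensemble$representatives

  lab_df <- data.frame(patient_id = patient_ids)
  for (i in seq_along(reps))
    lab_df[[paste0("representative_", i)]] <- reps[[i]]$labels
  if (length(reps) == 0) lab_df <- lab_df[0, , drop = FALSE]
  labels_path <- file.path(run_dir, "labels.csv")
  utils::write.csv(lab_df, labels_path, row.names = FALSE)

  stab_rows <- list()
  for (s in ensemble$candidates) {
    if (is.null(s$stability)) next
    pc <- s$stability$per_cluster
    stab_rows[[length(stab_rows) + 1L]] <- data.frame(
      stratification = combo_id(s), k = s$k, cluster = seq_along(pc),
      stability = as.numeric(pc), robust = s$stability$overall >=
        (ensemble$config$stability_threshold %||% 0.85))
  }
  stab_df <- if (length(stab_rows)) do.call(rbind, stab_rows) else
    data.frame(stratification = character(), k = integer(),
               cluster = integer(), stability = numeric(), robust = logical())
  stability_path <- file.path(run_dir, "stability.csv")
  utils::write.csv(stab_df, stability_path, row.names = FALSE)

  summ <- c(list(
    n_patients = length(patient_ids),
    n_candidates = length(ensemble$candidates),
    n_robust = length(ensemble$robust),
    n_groups = length(ensemble$groups),
    n_representatives = length(reps),
    no_robust_stratification = length(reps) == 0,
    representatives = lapply(reps, function(s)
      list(depth_id = s$depth_id, metric = s$metric, method = s$method,
           k = s$k))
  ), summary)
  summary_path <- file.path(run_dir, "summary.json")
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  log_path <- file.path(run_dir, "log.txt")
  writeLines(log_lines, log_path)
  invisible(c(labels = labels_path, stability = stability_path,
              summary = summary_path, log = log_path))
}
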
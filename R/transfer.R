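# Label transfer to external cohorts: kNN on reference-standardized
# signature columns, with K selected by cross-validated performance and
# majority voting across imputations of the target.

# Per-class vote fractions of the K nearest reference neighbours (Euclidean);
# predicted label is the majority, ties broken toward the label of the single
# nearest neighbour.
knn_votes <- function(ref, ref_labels, query, K) {
  ref_labels <- factor(ref_labels)
  cls <- levels(ref_labels)
  cross <- outer(rowSums(query^2), rowSums(ref^2), "+") -
    2 * tcrossprod(query, ref)
  cross[cross < 0] <- 0
  votes <- matrix(0, nrow(query), length(cls), dimnames = list(NULL, cls))
  pred <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    ord <- order(cross[i, ])
    nb <- ref_labels[ord[seq_len(K)]]
    v <- table(nb) / K
    votes[i, ] <- as.numeric(v)
    top <- names(v)[v == max(v)]
    pred[i] <- if (length(top) == 1) top else as.character(ref_labels[ord[1]])
  }
  list(pred = factor(pred, levels = cls), votes = votes)
}

#' Select the kNN neighbourhood size K by cross-validation
#'
#' Runs stratified cross-validation on the reference data for every candidate
#' K and reports accuracy, macro one-vs-rest AUC (from neighbour vote
#' fractions), error rate and per-class false positives / false negatives.
#' The chosen K maximizes accuracy, with ties broken toward higher AUC and
#' then toward the smaller K.
#'
#' @param reference numeric matrix of signature columns.
#' @param labels reference cluster labels (>= 2 classes).
#' @param candidates candidate K values.
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the fold split.
#' @return a `transfer_model`: standardized `reference`, `center`/`scale`,
#'   `labels`, selected `K` and the `report` data.frame.
#' @export
select_K <- function(reference, labels, candidates = c(3, 5, 7, 9, 11),
                     folds = 5, seed = 1) {
  stopifnot(length(candidates) >= 1, nrow(reference) >= folds)
  y <- factor(labels)
  if (min(table(y)) < folds)
    stop("class with fewer members (", min(table(y)), ") than folds (",
         folds, ")")
  ctr <- colMeans(reference)
  scl <- apply(reference, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance signature column")
  Xs <- scale(reference, ctr, scl)

  set.seed(seed)
  fold_of <- integer(nrow(Xs))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }

  report <- lapply(candidates, function(K) {
    pred <- factor(rep(NA_character_, nrow(Xs)), levels = levels(y))
    votes <- matrix(NA_real_, nrow(Xs), nlevels(y),
                    dimnames = list(NULL, levels(y)))
    for (fd in seq_len(folds)) {
      te <- fold_of == fd
      kv <- knn_votes(Xs[!te, , drop = FALSE], y[!te],
                      Xs[te, , drop = FALSE], K)
      pred[te] <- kv$pred
      votes[te, ] <- kv$votes
    }
    acc <- mean(pred == y)
    aucs <- vapply(levels(y), function(cl) {
      resp <- as.numeric(y == cl)
      as.numeric(pROC::auc(resp, votes[, cl], quiet = TRUE,
                           direction = "<", levels = c(0, 1)))
    }, numeric(1))
    fp <- vapply(levels(y), function(cl) sum(pred == cl & y != cl), numeric(1))
    fn <- vapply(levels(y), function(cl) sum(pred != cl & y == cl), numeric(1))
    data.frame(K = K, accuracy = acc, auc = mean(aucs),
               error_rate = 1 - acc, fp = sum(fp), fn = sum(fn))
  })
  report <- do.call(rbind, report)
  ord <- order(-report$accuracy, -report$auc, report$K)
  K_best <- report$K[ord[1]]
  structure(list(reference = Xs, center = ctr, scale = scl,
                 labels = y, K = K_best, report = report),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat("transfer_model: kNN with K=", x$K, ", ", nrow(x$reference),
      " reference patients, ", nlevels(x$labels), " classes\n", sep = "")
  invisible(x)
}

#' Transfer reference labels to a target cohort
#'
#' Each imputed target dataset is standardized with the reference means and
#' SDs and labelled by the model's kNN vote; the final label per patient is
#' the majority across imputations (ties broken toward the label with the
#' largest summed vote fraction) and `consistency` is the fraction of
#' imputations agreeing with the final label.
#'
#' @param model a `transfer_model` from [select_K()].
#' @param target_imputations list of complete numeric target matrices (or a
#'   single matrix) containing all signature columns.
#' @return list with `labels` (factor), `consistency` (numeric in `[0, 1]`)
#'   and `per_imputation` (label matrix).
#' @export
transfer_labels <- function(model, target_imputations) {
  stopifnot(inherits(model, "transfer_model"))
  if (is.matrix(target_imputations))
    target_imputations <- list(target_imputations)
  sig_cols <- colnames(model$reference)
  M <- length(target_imputations)
  cls <- levels(model$labels)
  n <- nrow(target_imputations[[1]])
  per_imp <- matrix(NA_character_, n, M)
  vote_sum <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
  for (i in seq_len(M)) {
    tm <- target_imputations[[i]]
    if (inherits(tm, "embedding")) tm <- tm$matrix
    missing_cols <- setdiff(sig_cols, colnames(tm))
    if (length(missing_cols))
      stop("target imputation ", i, " lacks signature column(s): ",
           paste(missing_cols, collapse = ", "))
    Xt <- scale(tm[, sig_cols, drop = FALSE], model$center, model$scale)
    kv <- knn_votes(model$reference, model$labels, Xt, model$K)
    per_imp[, i] <- as.character(kv$pred)
    vote_sum <- vote_sum + kv$votes
  }
  final <- vapply(seq_len(n), function(i) {
    tab <- table(factor(per_imp[i, ], levels = cls))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top
    else top[which.max(vote_sum[i, top])]
  }, character(1))
  consistency <- rowMeans(per_imp == final)
  list(labels = factor(final, levels = cls), consistency = consistency,
       per_imputation = per_imp)
}
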
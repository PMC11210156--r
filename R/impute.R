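# Chained-equations multiple imputation on an encoded cohort matrix.
#
# Each source feature is imputed by the conditional model matching its kind:
# predictive mean matching for numeric targets (imputed values are donated
# observed values), logistic regression for binary, multinomial logit for
# nominal and ordered logit for ordinal targets. Nominal features are imputed
# as units so their indicator columns keep summing to 1.

#' Multiple imputation by chained equations
#'
#' Produces `m` complete copies of an encoded cohort matrix. Within each
#' imputation, features with missing values are visited in order of
#' increasing missingness for `n_cycles` rounds; every target is regressed on
#' the encoded columns of its predictor features (all other features by
#' default, restrictable through `predictor_matrix`). Numeric targets use
#' predictive mean matching with a Bayesian draw of the regression
#' coefficients and `donors` nearest donors; binary targets a logistic draw;
#' nominal targets a multinomial-logit draw and ordinal targets an
#' ordered-logit draw (both fitted on a bootstrap resample of the observed
#' rows to propagate model uncertainty). Degenerate conditional models
#' (constant target, fit failure) fall back to a marginal draw and are
#' logged.
#'
#' @param encoded an `encoded_matrix` from [encode_cohort()].
#' @param m number of imputed datasets (>= 1).
#' @param seed integer seed; imputations are independent streams.
#' @param n_cycles chained-equation cycles per imputation.
#' @param predictor_matrix optional logical feature-by-feature matrix
#'   (rows = targets) selecting which features predict each target.
#' @param donors donor-pool size for predictive mean matching.
#' @param log optional run log.
#' @return an `imputation_set`: list with `m`, `datasets` (list of complete
#'   numeric matrices sharing the encoded column order), `provenance`,
#'   `schema`, `patient_ids`, `method_map` and `seed`.
#' @export
impute_chained <- function(encoded, m, seed = 1, n_cycles = 5,
                           predictor_matrix = NULL, donors = 5, log = NULL) {
  stopifnot(inherits(encoded, "encoded_matrix"), m >= 1, n_cycles >= 1)
  mat <- encoded$matrix
  prov <- encoded$provenance
  schema <- encoded$schema
  feats <- unique(prov$feature)
  feat_cols <- split(match(prov$column, colnames(mat)), prov$feature)[feats]
  kinds <- vapply(feats, function(f) schema[[f]]$kind, character(1))

  # feature-level missingness (encoded columns of a feature are NA together)
  fmiss <- vapply(feats, function(f) is.na(mat[, feat_cols[[f]][1]]),
                  logical(nrow(mat)))
  colnames(fmiss) <- feats
  if (any(colSums(!fmiss) == 0))
    stop("fully missing feature(s): ",
         paste(feats[colSums(!fmiss) == 0], collapse = ", "))
  targets <- feats[colSums(fmiss) > 0]
  targets <- targets[order(colSums(fmiss)[targets])]

  if (is.null(predictor_matrix)) {
    predictor_matrix <- matrix(TRUE, length(feats), length(feats),
                               dimnames = list(feats, feats))
    diag(predictor_matrix) <- FALSE
  }

  typed <- decode_encoded(mat, prov, schema)
  method_map <- c(numeric = "pmm", binary = "logreg",
                  nominal = "polyreg", ordinal = "polr")

  if (length(targets) == 0) {
    datasets <- rep(list(mat), m)
  } else {
    seeds <- derive_seeds(seed, m, stream = 11L)
    datasets <- vector("list", m)
    for (i in seq_len(m)) {
      set.seed(seeds[i])
      datasets[[i]] <- impute_once(mat, typed, fmiss, feats, feat_cols, kinds,
                                   schema, targets, predictor_matrix,
                                   n_cycles, donors, log)
    }
  }
  structure(list(m = m, datasets = datasets, provenance = prov,
                 schema = schema, patient_ids = encoded$patient_ids,
                 method_map = method_map, seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("imputation_set: m=", x$m, ", ", nrow(x$datasets[[1]]), " patients x ",
      ncol(x$datasets[[1]]), " encoded columns\n", sep = "")
  invisible(x)
}

# One complete dataset: initialize missing cells by marginal draws, then
# cycle conditional models. `cur_typed` carries feature-level values;
# `cur` the encoded matrix kept in sync.
impute_once <- function(mat, typed, fmiss, feats, feat_cols, kinds, schema,
                        targets, pred_mat, n_cycles, donors, log) {
  cur_typed <- typed
  for (f in targets) {
    mis <- fmiss[, f]
    obs_vals <- cur_typed[[f]][!mis]
    cur_typed[[f]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
  }
  cur <- reencode_typed(cur_typed, feats, feat_cols, kinds, schema, mat)

  for (cycle in seq_len(n_cycles)) {
    for (f in targets) {
      mis <- fmiss[, f]
      pred_feats <- feats[pred_mat[f, feats]]
      pcols <- unlist(feat_cols[pred_feats], use.names = FALSE)
      X <- cur[, pcols, drop = FALSE]
      X <- X[, apply(X, 2, function(c) stats::var(c) > 0), drop = FALSE]
      X <- cbind(`(Intercept)` = 1, X)
      drawn <- draw_feature(cur_typed[[f]], mis, X, kinds[f], schema[[f]],
                            donors, f, log)
      cur_typed[[f]][mis] <- drawn
      cur <- update_encoded(cur, cur_typed[[f]], f, feat_cols[[f]],
                            kinds[f], schema[[f]])
    }
  }
  cur
}

reencode_typed <- function(typed, feats, feat_cols, kinds, schema, template) {
  cur <- template
  for (f in feats)
    cur <- update_encoded(cur, typed[[f]], f, feat_cols[[f]], kinds[f],
                          schema[[f]])
  cur
}

update_encoded <- function(cur, values, f, cols, kind, feat) {
  if (kind == "numeric") {
    cur[, cols] <- values
  } else if (kind %in% c("binary", "ordinal")) {
    cur[, cols] <- match(values, feat$levels) - 1
  } else {
    for (j in seq_along(feat$levels))
      cur[, cols[j]] <- as.numeric(values == feat$levels[j])
  }
  cur
}

# Draw imputations for the missing entries of one feature.
draw_feature <- function(y, mis, X, kind, feat, donors, fname, log) {
  y_obs <- y[!mis]
  X_obs <- X[!mis, , drop = FALSE]
  X_mis <- X[mis, , drop = FALSE]
  n_mis <- sum(mis)

  marginal <- function(why) {
    log_msg(log, "imputation fallback (marginal draw) for '", fname, "': ", why)
    sample(y_obs, n_mis, replace = TRUE)
  }
  if (length(unique(y_obs)) < 2) return(marginal("constant observed values"))

  if (kind == "numeric") {
    out <- try(pmm_draw(y_obs, X_obs, X_mis, donors), silent = TRUE)
    if (inherits(out, "try-error")) return(marginal("pmm failure"))
    return(out)
  }
  if (kind == "binary") {
    out <- try(logreg_draw(y_obs, X_obs, X_mis, feat$levels), silent = TRUE)
    if (inherits(out, "try-error")) return(marginal("logistic failure"))
    return(out)
  }
  # categorical with >2 levels: bootstrap the observed rows, then draw from
  # the fitted class probabilities
  boot <- sample.int(length(y_obs), replace = TRUE)
  if (kind == "ordinal") {
    out <- try(polr_draw(y_obs, X_obs, X_mis, feat$levels, boot), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
    log_msg(log, "ordered-logit fit failed for '", fname,
            "', falling back to multinomial")
  }
  out <- try(polyreg_draw(y_obs, X_obs, X_mis, feat$levels, boot), silent = TRUE)
  if (inherits(out, "try-error")) return(marginal("multinomial failure"))
  out
}

# Predictive mean matching with a Bayesian parameter draw: predicted means
# for observed rows use beta-hat, for missing rows a posterior draw
# (beta-star, sigma-star); each missing value takes the observed value of a
# donor sampled among the `donors` closest predicted means.
pmm_draw <- function(y_obs, X_obs, X_mis, donors) {
  fit <- stats::lm.fit(X_obs, y_obs)
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  res <- fit$residuals
  df <- max(length(y_obs) - fit$rank, 1)
  sigma2_star <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  beta_star <- beta
  beta_star[piv] <- beta[piv] +
    backsolve(R, stats::rnorm(fit$rank)) * sqrt(sigma2_star)
  yhat_obs <- drop(X_obs %*% beta)
  yhat_mis <- drop(X_mis %*% beta_star)
  vapply(yhat_mis, function(v) {
    d <- abs(yhat_obs - v)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    y_obs[sample(pool, 1)]
  }, y_obs[1])
}

logreg_draw <- function(y_obs, X_obs, X_mis, levels) {
  y01 <- as.numeric(y_obs == levels[2])
  fit <- suppressWarnings(stats::glm.fit(X_obs, y01,
                                         family = stats::binomial()))
  beta <- fit$coefficients
  ok <- !is.na(beta)
  # approximate posterior draw from the estimated covariance
  Rq <- qr.R(fit$qr)
  cov <- tryCatch(chol2inv(Rq[seq_len(sum(ok)), seq_len(sum(ok)),
                              drop = FALSE]),
                  error = function(e) NULL)
  beta_star <- ifelse(ok, beta, 0)
  if (!is.null(cov)) {
    ch <- tryCatch(chol(cov), error = function(e) NULL)
    if (!is.null(ch))
      beta_star[ok] <- beta[ok] + drop(stats::rnorm(sum(ok)) %*% ch)
  }
  p <- stats::plogis(drop(X_mis %*% beta_star))
  levels[(stats::runif(nrow(X_mis)) < p) + 1L]
}

polyreg_draw <- function(y_obs, X_obs, X_mis, levels, boot) {
  df_fit <- data.frame(.y = factor(y_obs[boot], levels = levels),
                       X_obs[boot, -1, drop = FALSE], check.names = TRUE)
  fit <- nnet::multinom(.y ~ ., data = df_fit, trace = FALSE,
                        MaxNWts = 5000, maxit = 200)
  newd <- data.frame(X_mis[, -1, drop = FALSE], check.names = TRUE)
  names(newd) <- names(df_fit)[-1]
  pr <- stats::predict(fit, newdata = newd, type = "probs")
  lev_fit <- fit$lev
  if (is.null(dim(pr))) {
    pr <- if (length(lev_fit) == 2 && nrow(newd) > 1) {
      cbind(1 - pr, pr)           # binomial shortcut: P(second level) per row
    } else {
      matrix(pr, nrow = 1)        # single new observation
    }
    colnames(pr) <- lev_fit
  }
  apply(pr, 1, function(p) sample(colnames(pr), 1, prob = pmax(p, 0)))
}

polr_draw <- function(y_obs, X_obs, X_mis, levels, boot) {
  yb <- factor(y_obs[boot], levels = levels, ordered = TRUE)
  if (length(unique(yb)) < 3) stop("too few observed levels for ordered logit")
  df_fit <- data.frame(.y = yb, X_obs[boot, -1, drop = FALSE],
                       check.names = TRUE)
  fit <- suppressWarnings(MASS::polr(.y ~ ., data = df_fit, method = "logistic"))
  newd <- data.frame(X_mis[, -1, drop = FALSE], check.names = TRUE)
  names(newd) <- names(df_fit)[-1]
  pr <- stats::predict(fit, newdata = newd, type = "probs")
  if (is.null(dim(pr)))
    pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
  apply(pr, 1, function(p) sample(colnames(pr), 1, prob = pmax(p, 0)))
}
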
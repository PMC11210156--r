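# Minimal predictive signature: forward-backward feature selection with
# early dropping, using multinomial-logistic likelihood-ratio tests as the
# conditional-independence engine.

#' Minimal-size predictive signature for a stratification
#'
#' Forward phase: repeatedly add the candidate whose likelihood-ratio test
#' (multinomial logistic regression of the labels on selected + candidate vs.
#' selected alone) has the smallest p-value below `alpha`; candidates whose
#' test fails once are dropped from further consideration (early dropping).
#' Backward phase: iteratively remove any selected feature whose exclusion is
#' not significant at `alpha`. Deterministic given the input column order.
#' Quasi-separated fits are refit with a small ridge penalty and logged.
#'
#' @param features complete numeric matrix (one imputed or consolidated
#'   dataset), columns named.
#' @param labels cluster labels (>= 2 classes).
#' @param alpha significance level for the likelihood-ratio tests.
#' @param exclude column names barred from selection (e.g. severity scores).
#' @param log optional run log.
#' @return a `signature`: list with `selected` (ordered column names) and
#'   `trace` (per-step data.frame of tested features and p-values).
#' @export
minimal_signature <- function(features, labels, alpha = 0.05,
                              exclude = character(), log = NULL) {
  X <- if (inherits(features, "encoded_matrix")) features$matrix else features
  stopifnot(!anyNA(X), !is.null(colnames(X)))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("labels must have >= 2 classes")
  candidates <- setdiff(colnames(X), exclude)
  selected <- character()
  trace <- list()
  df1 <- nlevels(y) - 1

  # likelihood-ratio p-value for nested models on `small` vs `small + extra`;
  # both fits share the same (un)penalized criterion so the comparison stays
  # honest under quasi-separation
  cache <- new.env(parent = emptyenv())
  fit_cached <- function(cols, decay = 0) {
    key <- paste(c(decay, sort(cols)), collapse = "\r")
    f <- cache[[key]]
    if (is.null(f)) {
      f <- multinom_fit(X, y, cols, decay)
      cache[[key]] <- f
    }
    f
  }
  lrt_p <- function(small, big) {
    # a candidate aliased with the current model carries no information
    extra <- setdiff(big, small)
    if (length(extra) == 1 && is_aliased(X, small, extra)) return(1)
    f0 <- fit_cached(small)
    f1 <- fit_cached(big)
    if (f0$separated || f1$separated) {
      log_msg(log, "quasi-separation on {", paste(big, collapse = ","),
              "}; penalized refit of both nested models")
      f0 <- fit_cached(small, decay = 0.05)
      f1 <- fit_cached(big, decay = 0.05)
    }
    stats::pchisq(max(f0$deviance - f1$deviance, 0),
                  df = df1 * length(extra), lower.tail = FALSE)
  }

  # forward with early dropping
  active <- candidates
  step <- 0L
  while (length(active)) {
    step <- step + 1L
    pvals <- vapply(active, function(f)
      lrt_p(selected, c(selected, f)), numeric(1))
    trace[[length(trace) + 1L]] <- data.frame(
      phase = "forward", step = step, feature = active, p = unname(pvals))
    ok <- pvals < alpha
    if (!any(ok)) break
    best <- active[which.min(pvals)]
    selected <- c(selected, best)
    active <- setdiff(active[ok], best)   # early dropping: failures leave
  }

  # backward: drop features whose exclusion is not significant
  repeat {
    if (length(selected) < 1) break
    pvals <- vapply(selected, function(f)
      lrt_p(setdiff(selected, f), selected), numeric(1))
    trace[[length(trace) + 1L]] <- data.frame(
      phase = "backward", step = step, feature = selected, p = unname(pvals))
    worst <- which.max(pvals)
    if (pvals[worst] >= alpha) selected <- selected[-worst] else break
  }
  structure(list(selected = selected, trace = do.call(rbind, trace),
                 alpha = alpha),
            class = "signature")
}

# TRUE when `extra` is (numerically) a linear combination of the intercept
# and the already-selected columns.
is_aliased <- function(X, selected, extra) {
  v <- X[, extra]
  if (stats::var(v) == 0) return(TRUE)
  if (length(selected) == 0) return(FALSE)
  fit <- stats::lm.fit(cbind(1, X[, selected, drop = FALSE]), v)
  resid_var <- sum(fit$residuals^2) / sum((v - mean(v))^2)
  resid_var < 1e-8
}

#' @export
print.signature <- function(x, ...) {
  if (length(x$selected))
    cat("signature (", length(x$selected), " features): ",
        paste(x$selected, collapse = ", "), "\n", sep = "")
  else cat("signature: empty (no feature passed alpha = ", x$alpha, ")\n",
           sep = "")
  invisible(x)
}

# Multinomial logistic fit of y on the given columns (standardized).
# Flags quasi-separation through exploding coefficients.
multinom_fit <- function(X, y, cols, decay = 0) {
  if (length(cols) == 0) {
    p <- as.numeric(table(y)) / length(y)
    return(list(deviance = -2 * sum(log(p)[as.integer(y)]),
                separated = FALSE))
  }
  df <- data.frame(.y = y, scale(X[, cols, drop = FALSE]), check.names = TRUE)
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300,
                        MaxNWts = 5000, decay = decay)
  list(deviance = fit$deviance,
       separated = decay == 0 && max(abs(stats::coef(fit))) > 15)
}
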
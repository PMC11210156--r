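# Patient-to-patient dissimilarities on an embedding.

#' Correlation-based distance between patients
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation between the two
#' patients' embedding rows; values lie in `[0, 2]`.
#'
#' @param embedding an `embedding` or numeric matrix (patients x components,
#'   at least 2 components).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
correlation_distance <- function(embedding) {
  X <- if (inherits(embedding, "embedding")) embedding$matrix else embedding
  if (ncol(X) < 2) stop("correlation distance requires >= 2 components")
  # r(i, j) via one BLAS product on row-standardized rows
  p <- ncol(X)
  mu <- rowMeans(X)
  rsd <- sqrt(rowSums((X - mu)^2) / (p - 1))
  if (any(rsd == 0))
    stop("constant patient row(s) (undefined correlation): ",
         paste(which(rsd == 0), collapse = ", "))
  Xz <- (X - mu) / rsd
  D <- 1 - tcrossprod(Xz) / (p - 1)
  D[D < 0] <- 0
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Gower dissimilarity between patients
#'
#' Each column contributes `|x_i - x_j| / range(column)`; for a two-valued
#' (passthrough binary) column this reduces to the simple mismatch indicator.
#' The Gower dissimilarity is the mean contribution, so values lie in
#' `[0, 1]`.
#'
#' @param embedding an `embedding` or numeric matrix.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
gower_distance <- function(embedding) {
  X <- if (inherits(embedding, "embedding")) embedding$matrix else embedding
  rng <- apply(X, 2, function(c) diff(range(c)))
  if (any(rng == 0))
    stop("zero-range column(s): ",
         paste(colnames(X)[rng == 0], collapse = ", "))
  Xs <- sweep(X, 2, rng, "/")
  D <- as.matrix(stats::dist(Xs, method = "manhattan")) / ncol(X)
  diag(D) <- 0
  D
}

#' Compute a patient distance matrix by metric name
#' @param embedding an `embedding` or numeric matrix.
#' @param metric `"correlation"` or `"gower"`.
#' @return symmetric dissimilarity matrix.
#' @export
patient_distance <- function(embedding, metric = c("correlation", "gower")) {
  metric <- match.arg(metric)
  if (metric == "correlation") correlation_distance(embedding)
  else gower_distance(embedding)
}
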
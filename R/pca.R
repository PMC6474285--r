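#' Principal component analysis
#'
#' Thin SVD-based PCA on a scaled bucket matrix: columns are mean-centered,
#' loadings are the right singular vectors, scores the projections, and the
#' explained-variance fractions the normalized squared singular values.
#'
#' @param X Numeric matrix (samples x variables) or [new_bucket_table()];
#'   typically Pareto-scaled. Non-finite entries are rejected.
#' @param n_components Number of components, at most `min(samples - 1,
#'   variables)`.
#' @return List of class `pca_model`: `loadings` (orthonormal columns),
#'   `scores`, `explained_variance_fraction`, `center`.
#' @export
fit_pca <- function(X, n_components = 2) {
  if (inherits(X, "bucket_table")) X <- X$values
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite", call. = FALSE)
  if (n_components > min(nrow(X) - 1L, ncol(X))) {
    stop("n_components exceeds min(samples - 1, variables)", call. = FALSE)
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  evf <- sv$d^2 / sum(sv$d^2)
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  # sign convention: largest-|loading| variable positive per component
  for (j in k) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(X)
  scores <- Xc %*% loadings
  rownames(scores) <- rownames(X)
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_fraction = evf[k], center = center),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d component(s); explained: %s\n",
              ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}
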
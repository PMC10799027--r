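# Principal component analysis via mean-centred SVD.

#' Fit a PCA model
#'
#' Mean-centres the rows and takes the singular value decomposition.
#' Explained-variance ratios are relative to the total variance (so the
#' retained ratios sum to <= 1). Sign convention: each loading's
#' largest-magnitude entry is positive, so loadings compare
#' deterministically against oracles and across runs.
#'
#' @param x Numeric matrix, one observation (spectrum) per row.
#' @param n_components Components to retain; default 15, which in the
#'   intended spectral datasets captures over 90% of the variance.
#' @return A `pca_model`: `mean`, `loadings` (columns, orthonormal),
#'   `explained_variance_ratio`, `singular_values`, `n_components`, `n_obs`.
#' @export
fit_pca <- function(x, n_components = 15) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("PCA needs at least 2 observations")
  max_k <- min(n - 1L, ncol(x))
  if (n_components > max_k) {
    stop("n_components = ", n_components, " exceeds the maximum ", max_k,
         " for a ", n, " x ", ncol(x), " matrix")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0, nv = max_k)
  d2 <- sv$d^2
  evr <- d2[seq_len(n_components)] / sum(d2)
  loadings <- sv$v[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) loadings[, j] <- -loadings[, j]
  }
  structure(
    list(mean = mu, loadings = loadings,
         explained_variance_ratio = evr,
         singular_values = sv$d[seq_len(n_components)],
         n_components = as.integer(n_components), n_obs = n),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d points; cumulative variance %.1f%%\n",
              x$n_components, length(x$mean),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project data onto a fitted PCA model
#'
#' @param model A `pca_model`.
#' @param x Matrix on the model's grid (one row per observation) or a
#'   single numeric vector.
#' @return Score matrix (`n x n_components`).
#' @export
transform_pca <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == length(model$mean))
  sweep(as.matrix(x), 2, model$mean) %*% model$loadings
}

#' Reconstruct data from PCA scores
#'
#' @param model A `pca_model`.
#' @param scores Score matrix.
#' @return Reconstructed matrix on the original grid.
#' @export
inverse_transform_pca <- function(model, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  sweep(scores %*% t(model$loadings), 2, model$mean, `+`)
}

#' Cumulative explained-variance fractions
#'
#' @param model A `pca_model`.
#' @return Non-decreasing numeric vector, one entry per retained component,
#'   last entry <= 1.
#' @export
cumulative_variance <- function(model) {
  cumsum(model$explained_variance_ratio)
}
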
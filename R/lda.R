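# Linear discriminant analysis in PCA-score space: maximise between-class
# scatter against (ridge-regularised) pooled within-class scatter; classify
# by nearest class mean in the discriminant space.

#' Fit an LDA model
#'
#' Solves the generalized eigenproblem Sb v = lambda (Sw + reg I) v via
#' symmetric whitening of the within-class scatter, keeping up to
#' `n_classes - 1` discriminant axes sorted by decreasing eigenvalue. Axis
#' signs follow the largest-magnitude-entry-positive convention.
#'
#' @param scores Numeric matrix, one observation per row (typically PCA
#'   scores).
#' @param labels Class label per row; >= 2 classes, each with >= 2
#'   samples.
#' @param lambda Ridge added to the within-class scatter for numerical
#'   stability; default 1e-6.
#' @return An `lda_model`: `class_labels` (sorted), `class_means` (in
#'   score space), `axes` (columns), `eigenvalues`, `class_means_proj`,
#'   `lambda`.
#' @export
fit_lda <- function(scores, labels, lambda = 1e-6) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("LDA needs at least 2 classes")
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop("class '", small[1], "' has fewer than 2 samples")
  }
  d <- ncol(scores)
  mu <- colMeans(scores)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  M <- matrix(NA_real_, length(classes), d,
              dimnames = list(classes, NULL))
  for (cls in classes) {
    rows <- scores[labels == cls, , drop = FALSE]
    mc <- colMeans(rows)
    M[cls, ] <- mc
    centred <- sweep(rows, 2, mc)
    Sw <- Sw + crossprod(centred)
    Sb <- Sb + nrow(rows) * tcrossprod(mc - mu)
  }
  Swr <- Sw + lambda * diag(d)
  es <- eigen(Swr, symmetric = TRUE)
  # whitening transform W = U D^-1/2 U'
  W <- es$vectors %*% diag(1 / sqrt(pmax(es$values, .Machine$double.eps)),
                           d) %*% t(es$vectors)
  Mb <- W %*% Sb %*% W
  eb <- eigen((Mb + t(Mb)) / 2, symmetric = TRUE)
  n_axes <- min(length(classes) - 1L, d)
  axes <- W %*% eb$vectors[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(ncol(axes))) {
    i_max <- which.max(abs(axes[, j]))
    if (axes[i_max, j] < 0) axes[, j] <- -axes[, j]
  }
  structure(
    list(class_labels = classes, class_means = M, axes = axes,
         eigenvalues = eb$values[seq_len(n_axes)],
         class_means_proj = M %*% axes, lambda = lambda,
         Sw = Sw, Sb = Sb),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes, %d discriminant axes\n",
              length(x$class_labels), ncol(x$axes)))
  invisible(x)
}

#' Project observations into the discriminant space
#'
#' @param model An `lda_model`.
#' @param scores Matrix of observations (rows) in the model's input space.
#' @return Matrix of discriminant coordinates.
#' @export
transform_lda <- function(model, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  as.matrix(scores) %*% model$axes
}

#' Classify by nearest class mean in discriminant space
#'
#' Euclidean distance to each class mean's projection; ties are broken by
#' class-label order (deterministic).
#'
#' @param model An `lda_model`.
#' @param scores Matrix of observations in the model's input space.
#' @return Character vector of predicted class labels.
#' @export
predict_lda <- function(model, scores) {
  proj <- transform_lda(model, scores)
  cm <- model$class_means_proj
  out <- character(nrow(proj))
  for (i in seq_len(nrow(proj))) {
    d2 <- rowSums(sweep(cm, 2, proj[i, ])^2)
    out[i] <- model$class_labels[which.min(d2)]  # which.min: first on ties
  }
  out
}
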
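# Stratified k-fold cross-validation of the PCA-LDA classifier, and
# confusion-matrix metrics.

#' Stratified k-fold assignment
#'
#' Partitions indices into `k` folds preserving class proportions: within
#' each class, indices are shuffled (seed-driven) and dealt to folds
#' round-robin, so per-class fold sizes differ by at most one.
#'
#' @param labels Class label per observation.
#' @param k Number of folds; default 4.
#' @param seed Seed driving the within-class shuffles.
#' @return Integer fold index (1..k) per observation.
#' @export
stratified_kfold <- function(labels, k = 4, seed = 1) {
  labels <- as.character(labels)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop("class '", small[1], "' has ", counts[small[1]],
         " members, fewer than k = ", k)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Confusion-matrix metrics
#'
#' From a square non-negative count matrix (rows = true class, columns =
#' predicted class): per-class recall (diagonal over row sum), precision
#' (diagonal over column sum), F1 (harmonic mean), and average accuracy
#' defined as the unweighted mean of per-class recalls. The overall
#' (weighted) accuracy, the trace over the total, is reported alongside.
#' A zero row or column denominator yields 0 for the affected metric, with
#' the class recorded in `zero_denominator`.
#'
#' @param counts Square non-negative count matrix, ideally with dimnames
#'   giving the class labels.
#' @return A list: `confusion` (row-normalized), `recall`, `precision`,
#'   `f1`, `average_accuracy`, `weighted_accuracy`, `zero_denominator`.
#' @export
confusion_metrics <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("count matrix must be square")
  if (any(counts < 0)) stop("count matrix must be non-negative")
  labels <- rownames(counts) %||% paste0("class", seq_len(nrow(counts)))
  rs <- rowSums(counts)
  cs <- colSums(counts)
  dg <- diag(counts)
  recall <- ifelse(rs > 0, dg / rs, 0)
  precision <- ifelse(cs > 0, dg / cs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  confusion <- counts
  nonzero <- rs > 0
  confusion[nonzero, ] <- counts[nonzero, , drop = FALSE] / rs[nonzero]
  names(recall) <- names(precision) <- names(f1) <- labels
  dimnames(confusion) <- list(labels, labels)
  list(confusion = confusion,
       recall = recall, precision = precision, f1 = f1,
       average_accuracy = mean(recall),
       weighted_accuracy = if (sum(counts) > 0) sum(dg) / sum(counts) else 0,
       zero_denominator = labels[rs == 0 | cs == 0])
}

#' Cross-validate the PCA-LDA classifier
#'
#' Stratified k-fold cross-validation. Within each fold, PCA is fitted on
#' the training rows only, both partitions are projected, LDA is fitted on
#' the training scores, and the held-out rows are predicted — so PCA and
#' LDA never see test rows. Held-out predictions from all folds are pooled
#' into one count matrix, reported row-normalized (rows = true class).
#'
#' @param dataset A [spectral_dataset()], already preprocessed (typically
#'   truncated to the fingerprint region).
#' @param n_components PCA components per fold; default 15 (silently capped
#'   at the per-fold maximum, recorded in the report).
#' @param k Folds; default 4.
#' @param lambda LDA ridge; default 1e-6.
#' @param seed Seed for the fold assignment.
#' @return A `cv_report`: `fold_assignments`, `counts`, `confusion`
#'   (row-normalized), `recall`, `precision`, `f1`, `average_accuracy`,
#'   `weighted_accuracy`, `per_class_accuracy` (= recall), `predictions`
#'   (data frame id, true, predicted, fold), `n_components_used`, `seed`.
#' @export
cross_validate <- function(dataset, n_components = 15, k = 4,
                           lambda = 1e-6, seed = 1) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  labels <- dataset$labels
  classes <- sort(unique(labels))
  folds <- stratified_kfold(labels, k = k, seed = seed)
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  predicted <- character(length(labels))
  ncomp_used <- integer(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    x_tr <- dataset$matrix[tr, , drop = FALSE]
    ncomp <- min(n_components, nrow(x_tr) - 1L, ncol(x_tr))
    ncomp_used[f] <- ncomp
    pca <- fit_pca(x_tr, n_components = ncomp)
    s_tr <- transform_pca(pca, x_tr)
    s_te <- transform_pca(pca, dataset$matrix[te, , drop = FALSE])
    lda <- fit_lda(s_tr, labels[tr], lambda = lambda)
    pred <- predict_lda(lda, s_te)
    predicted[te] <- pred
    for (i in seq_along(pred)) {
      counts[labels[te][i], pred[i]] <- counts[labels[te][i], pred[i]] + 1L
    }
  }
  met <- confusion_metrics(counts)
  structure(
    c(list(fold_assignments = folds, counts = counts,
           predictions = data.frame(id = dataset$ids, true = labels,
                                    predicted = predicted, fold = folds,
                                    stringsAsFactors = FALSE),
           per_class_accuracy = met$recall,
           n_components_used = ncomp_used, seed = seed),
      met),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold stratified CV, %d spectra, %d classes\n",
    length(unique(x$fold_assignments)), length(x$fold_assignments),
    nrow(x$confusion)))
  cat(sprintf("  average accuracy (mean per-class recall): %.1f%%\n",
              100 * x$average_accuracy))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Export a cross-validation report to CSV/JSON files
#'
#' Writes `confusion.csv` (row-normalized), `counts.csv`, `metrics.json`
#' (recall/precision/F1/average accuracy per class) and
#' `predictions.csv` into `dir`.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cv_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$confusion, file.path(dir, "confusion.csv"))
  utils::write.csv(report$counts, file.path(dir, "counts.csv"))
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(recall = as.list(report$recall),
         precision = as.list(report$precision),
         f1 = as.list(report$f1),
         average_accuracy = report$average_accuracy,
         weighted_accuracy = report$weighted_accuracy,
         seed = report$seed),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
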
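# Extended multiplicative signal correction (EMSC) with interferent
# removal. Model per spectrum:
#   s(nu) = b * r(nu) + sum_p c_p x(nu)^p + sum_k g_k i_k(nu) + e(nu)
# where r is the reference spectrum, x is the wavenumber axis rescaled to
# [-1, 1] (conditioning of the polynomial columns), and i_k are known
# interferent spectra (here the PDMS chip background). Solved by ordinary
# least squares; the corrected spectrum is
#   (s - polynomial - interferents) / b.

emsc_design <- function(grid, reference, interferents, poly_order) {
  x <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  cols <- list(reference = reference)
  for (p in 0:poly_order) cols[[paste0("poly", p)]] <- x^p
  if (length(interferents)) {
    for (k in seq_along(interferents)) {
      cols[[paste0("interferent", k)]] <- interferents[[k]]
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Fit the EMSC model to one spectrum
#'
#' @param spectrum A [raman_spectrum()] or numeric intensity vector.
#' @param reference Reference intensity on the same grid (typically the
#'   dataset mean spectrum), as a [raman_spectrum()] or numeric vector.
#' @param interferents List of interferent spectra on the same grid
#'   (numeric vectors or [raman_spectrum()]s); may be empty.
#' @param poly_order Polynomial baseline order P (columns x^0..x^P on the
#'   axis rescaled to \[-1, 1\]); default 2.
#' @param grid Wavenumber grid; required when `spectrum` is a bare vector.
#' @return An `emsc_fit`: `b` (multiplicative scale), `c` (polynomial
#'   coefficients, orders 0..P), `g` (interferent weights), `corrected`
#'   ([raman_spectrum()] on the input axis), `residual_norm` (RMS
#'   residual), `degenerate` (TRUE when b <= 0).
#' @export
fit_emsc <- function(spectrum, reference, interferents = list(),
                     poly_order = 2, grid = NULL) {
  if (inherits(spectrum, "raman_spectrum")) {
    grid <- spectrum$wavenumber
    y <- spectrum$intensity
    meta <- spectrum$meta
  } else {
    y <- as.numeric(spectrum)
    if (is.null(grid)) stop("grid must be supplied for a bare vector")
    meta <- list(id = "spectrum", stage = NA_character_, window = NULL,
                 calibration_shift = 0)
  }
  as_vec <- function(s) if (inherits(s, "raman_spectrum")) s$intensity else
    as.numeric(s)
  r <- as_vec(reference)
  ints <- lapply(interferents, as_vec)
  stopifnot(length(r) == length(y))
  for (v in ints) stopifnot(length(v) == length(y))

  X <- emsc_design(grid, r, ints, poly_order)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-seq_len(qrX$rank)]
    pivoted <- colnames(X)[qrX$pivot[seq_len(qrX$rank)]]
    stop("EMSC design matrix is rank deficient; collinear column(s): ",
         paste(setdiff(colnames(X), pivoted), collapse = ", "))
  }
  coef <- qr.coef(qrX, y)
  b <- coef[["reference"]]
  cpoly <- coef[grep("^poly", names(coef))]
  gint <- coef[grep("^interferent", names(coef))]
  if (abs(b) < 1e-10) {
    stop("degenerate EMSC fit: multiplicative scale b is ~0")
  }
  modelled_bg <- X[, -1, drop = FALSE] %*% coef[-1]
  corrected <- (y - as.numeric(modelled_bg)) / b
  resid <- y - as.numeric(X %*% coef)
  structure(
    list(b = unname(b), c = unname(cpoly), g = unname(gint),
         corrected = raman_spectrum(grid, corrected, id = meta$id,
                                    stage = meta$stage,
                                    window = meta$window,
                                    calibration_shift =
                                      meta$calibration_shift),
         residual_norm = sqrt(mean(resid^2)),
         degenerate = b <= 0),
    class = "emsc_fit"
  )
}

#' @export
print.emsc_fit <- function(x, ...) {
  cat(sprintf("<emsc_fit> b=%.4g, poly=(%s), g=(%s), rms resid=%.3g%s\n",
              x$b, paste(sprintf("%.3g", x$c), collapse = ", "),
              paste(sprintf("%.3g", x$g), collapse = ", "),
              x$residual_norm,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' EMSC-correct a whole dataset against its mean spectrum
#'
#' The reference is the dataset mean spectrum, computed once before any
#' correction (and never per class, so preprocessing sees no labels).
#' Spectra whose fit is degenerate (b <= 0) are flagged in the fit table
#' and passed through uncorrected rather than dropped.
#'
#' @param dataset A [spectral_dataset()].
#' @param interferents List of interferent spectra on the dataset grid.
#' @param poly_order Polynomial order; default 2.
#' @return A list: `dataset` (corrected), `fits` (data frame of b,
#'   polynomial coefficients, interferent weights, residual norm and the
#'   degenerate flag per spectrum), `reference` (the mean spectrum used).
#' @export
emsc_correct_dataset <- function(dataset, interferents = list(),
                                 poly_order = 2) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (n_spectra(dataset) == 0) stop("cannot EMSC-correct an empty dataset")
  reference <- colMeans(dataset$matrix)
  out <- dataset$matrix
  n <- n_spectra(dataset)
  nint <- length(interferents)
  fits <- data.frame(id = dataset$ids, b = NA_real_,
                     residual_norm = NA_real_, degenerate = FALSE,
                     failed = FALSE, stringsAsFactors = FALSE)
  cmat <- matrix(NA_real_, n, poly_order + 1,
                 dimnames = list(NULL, paste0("c", 0:poly_order)))
  gmat <- if (nint) matrix(NA_real_, n, nint,
                           dimnames = list(NULL, paste0("g", seq_len(nint))))
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_emsc(dataset$matrix[i, ], reference, interferents,
               poly_order, grid = dataset$grid),
      error = function(e) e)
    if (inherits(fit, "error")) {
      fits$failed[i] <- TRUE
      next
    }
    out[i, ] <- fit$corrected$intensity
    fits$b[i] <- fit$b
    fits$residual_norm[i] <- fit$residual_norm
    fits$degenerate[i] <- fit$degenerate
    cmat[i, ] <- fit$c
    if (nint) gmat[i, ] <- fit$g
  }
  fits <- cbind(fits, cmat)
  if (nint) fits <- cbind(fits, gmat)
  list(dataset = spectral_dataset(dataset$grid, out, dataset$labels,
                                  dataset$ids),
       fits = fits,
       reference = raman_spectrum(dataset$grid, reference,
                                  id = "emsc-reference"))
}
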
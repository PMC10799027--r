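#' Construct a single Raman spectrum
#'
#' A `raman_spectrum` is one cell's Raman trace: a strictly increasing
#' wavenumber axis (cm^-1) with one intensity per grid point, plus free-form
#' metadata (spectrum id, disease-stage label, acquisition-window tag,
#' calibration shift already applied).
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumber`, all finite.
#' @param id Spectrum identifier (character scalar).
#' @param stage Optional disease-stage label (e.g. `"HET-1A"`).
#' @param window Optional acquisition-window tag per grid point or scalar
#'   (e.g. `"low"` for the 300-1800 cm^-1 window).
#' @param calibration_shift Wavenumber shift in cm^-1 already applied to the
#'   axis (0 for uncalibrated data).
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, id = "spectrum",
                           stage = NA_character_, window = NULL,
                           calibration_shift = 0) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have equal length (got ",
         length(wavenumber), " and ", length(intensity), ")")
  }
  if (length(wavenumber) < 2L) {
    stop("a spectrum needs at least 2 grid points")
  }
  if (anyNA(wavenumber) || any(!is.finite(wavenumber))) {
    stop("wavenumber axis contains non-finite values")
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("intensity contains non-finite values")
  }
  d <- diff(wavenumber)
  if (any(d <= 0)) {
    stop("wavenumber axis must be strictly increasing; first violation at row ",
         which(d <= 0)[1] + 1L)
  }
  structure(
    list(
      wavenumber = wavenumber,
      intensity = intensity,
      meta = list(id = as.character(id), stage = stage, window = window,
                  calibration_shift = calibration_shift)
    ),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumber)
  cat(sprintf(
    "<raman_spectrum> id=%s stage=%s  %d points, %.1f-%.1f cm^-1\n",
    x$meta$id, x$meta$stage %||% NA, length(x$wavenumber), rng[1], rng[2]))
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a spectral dataset
#'
#' A `spectral_dataset` holds spectra resampled to one shared wavenumber
#' grid as an `n_spectra x n_points` matrix, with a disease-stage label and
#' an id per spectrum (row).
#'
#' @param grid Shared wavenumber axis (cm^-1), strictly increasing.
#' @param matrix Numeric matrix, one spectrum per row, `length(grid)` columns.
#' @param labels Stage label per row.
#' @param ids Spectrum id per row (unique).
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(grid, matrix, labels, ids) {
  grid <- as.numeric(grid)
  matrix <- as.matrix(matrix)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (ncol(matrix) != length(grid)) {
    stop("matrix has ", ncol(matrix), " columns but grid has ",
         length(grid), " points")
  }
  n <- nrow(matrix)
  if (length(labels) != n || length(ids) != n) {
    stop("labels and ids must match the number of rows (", n, ")")
  }
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("dataset matrix contains non-finite values")
  }
  if (anyDuplicated(ids)) stop("spectrum ids must be unique")
  dimnames(matrix) <- list(as.character(ids), NULL)
  structure(
    list(grid = grid, matrix = matrix,
         labels = as.character(labels), ids = as.character(ids)),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  rng <- range(x$grid)
  cat(sprintf("<spectral_dataset> %d spectra x %d points, %.1f-%.1f cm^-1\n",
              nrow(x$matrix), length(x$grid), rng[1], rng[2]))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of spectra in a dataset
#' @param x A `spectral_dataset`.
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(x) nrow(x$matrix)

#' Subset a spectral dataset by row
#'
#' @param x A `spectral_dataset`.
#' @param i Row indices or logical mask.
#' @return A `spectral_dataset` with the selected spectra.
#' @export
subset_dataset <- function(x, i) {
  spectral_dataset(x$grid, x$matrix[i, , drop = FALSE],
                   x$labels[i], x$ids[i])
}

#' Extract one spectrum from a dataset
#' @param x A `spectral_dataset`.
#' @param i Row index or id.
#' @return A `raman_spectrum`.
#' @export
get_spectrum <- function(x, i) {
  if (is.character(i)) i <- match(i, x$ids)
  raman_spectrum(x$grid, x$matrix[i, ], id = x$ids[i], stage = x$labels[i])
}
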
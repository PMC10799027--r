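# Truncation, Amide I normalization, Savitzky-Golay smoothing and
# variance-based outlier removal — the tail of the preprocessing chain.

#' Truncate a spectrum or dataset to a wavenumber interval
#'
#' Retains grid points in the closed interval `[lo, hi]`; defaults select
#' the biochemically dense fingerprint region 800-1800 cm^-1.
#'
#' @param x A [raman_spectrum()] or [spectral_dataset()].
#' @param lo,hi Interval bounds in cm^-1.
#' @return The same kind of object, restricted to the interval.
#' @export
truncate_range <- function(x, lo = 800, hi = 1800) {
  stopifnot(lo <= hi)
  if (inherits(x, "raman_spectrum")) {
    keep <- x$wavenumber >= lo & x$wavenumber <= hi
    if (!any(keep)) {
      stop("truncation interval [", lo, ", ", hi,
           "] does not intersect the grid")
    }
    if (sum(keep) == 1) {
      # degenerate single-point result: return it as a bare pairing since
      # raman_spectrum requires >= 2 points
      return(list(wavenumber = x$wavenumber[keep],
                  intensity = x$intensity[keep]))
    }
    raman_spectrum(x$wavenumber[keep], x$intensity[keep],
                   id = x$meta$id, stage = x$meta$stage,
                   window = if (!is.null(x$meta$window) &&
                                length(x$meta$window) == length(keep))
                     x$meta$window[keep] else x$meta$window,
                   calibration_shift = x$meta$calibration_shift)
  } else if (inherits(x, "spectral_dataset")) {
    keep <- x$grid >= lo & x$grid <= hi
    if (!any(keep)) {
      stop("truncation interval [", lo, ", ", hi,
           "] does not intersect the grid")
    }
    spectral_dataset(x$grid[keep], x$matrix[, keep, drop = FALSE],
                     x$labels, x$ids)
  } else {
    stop("truncate_range expects a raman_spectrum or spectral_dataset")
  }
}

#' Normalize to the Amide I band
#'
#' Divides all intensities by the maximum intensity within
#' `anchor +/- half_window` cm^-1 (the windowed peak maximum tolerates
#' ~1 cm^-1 residual calibration drift better than the single grid value at
#' the anchor). After normalization that maximum equals 1; the operation is
#' idempotent.
#'
#' @param x A [raman_spectrum()] or [spectral_dataset()] (normalized per
#'   row).
#' @param anchor Anchor wavenumber; default 1656 cm^-1 (Amide I).
#' @param half_window Half-width of the closed search window in cm^-1.
#' @return Same kind of object, normalized.
#' @export
normalize_amide_i <- function(x, anchor = 1656, half_window = 5) {
  norm_one <- function(grid, y) {
    win <- grid >= anchor - half_window & grid <= anchor + half_window
    if (!any(win)) {
      stop("normalization window ", anchor, " +/- ", half_window,
           " cm^-1 lies outside the grid")
    }
    m <- max(y[win])
    if (m <= 0) {
      stop("normalizing intensity at the Amide I window is <= 0; ",
           "spectrum unusable")
    }
    y / m
  }
  if (inherits(x, "raman_spectrum")) {
    raman_spectrum(x$wavenumber, norm_one(x$wavenumber, x$intensity),
                   id = x$meta$id, stage = x$meta$stage,
                   window = x$meta$window,
                   calibration_shift = x$meta$calibration_shift)
  } else if (inherits(x, "spectral_dataset")) {
    out <- x$matrix
    for (i in seq_len(n_spectra(x))) {
      out[i, ] <- tryCatch(norm_one(x$grid, x$matrix[i, ]),
                           error = function(e)
                             stop("spectrum '", x$ids[i], "': ",
                                  conditionMessage(e), call. = FALSE))
    }
    spectral_dataset(x$grid, out, x$labels, x$ids)
  } else {
    stop("normalize_amide_i expects a raman_spectrum or spectral_dataset")
  }
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (default polynomial order 2,
#' window 17 points). Endpoints are handled by the edge polynomial fits, so
#' a polynomial of the fitted degree is reproduced exactly everywhere.
#'
#' @param x A [raman_spectrum()] or [spectral_dataset()] (smoothed per
#'   row).
#' @param poly_order Polynomial order; default 2.
#' @param window Window length in points; odd, > `poly_order`, <= spectrum
#'   length.
#' @return Same kind of object, smoothed.
#' @export
smooth_spectrum <- function(x, poly_order = 2, window = 17) {
  npts <- if (inherits(x, "raman_spectrum")) length(x$wavenumber) else
    length(x$grid)
  if (window %% 2 == 0) stop("smoothing window must be odd (got ", window, ")")
  if (window <= poly_order) {
    stop("smoothing window (", window, ") must exceed the polynomial order (",
         poly_order, ")")
  }
  if (window > npts) {
    stop("smoothing window (", window, ") exceeds the spectrum length (",
         npts, ")")
  }
  if (inherits(x, "raman_spectrum")) {
    raman_spectrum(x$wavenumber,
                   signal::sgolayfilt(x$intensity, p = poly_order,
                                      n = window),
                   id = x$meta$id, stage = x$meta$stage,
                   window = x$meta$window,
                   calibration_shift = x$meta$calibration_shift)
  } else if (inherits(x, "spectral_dataset")) {
    out <- t(apply(x$matrix, 1, signal::sgolayfilt, p = poly_order,
                   n = window))
    spectral_dataset(x$grid, out, x$labels, x$ids)
  } else {
    stop("smooth_spectrum expects a raman_spectrum or spectral_dataset")
  }
}

#' Remove high-variance outlier spectra per class
#'
#' Scores each spectrum by its squared Euclidean distance from its class
#' mean spectrum. In target mode (`target_n`) the highest-scoring spectra
#' are removed per class until `target_n` remain; in MAD mode (`mad_k`)
#' spectra with score above `median + mad_k * MAD` of their class are
#' removed. Removals are deterministic: score ties are broken by spectrum
#' id order.
#'
#' @param dataset A [spectral_dataset()].
#' @param target_n Per-class target count (default mode, 100, echoing a
#'   final dataset of roughly one hundred single-cell spectra per cell
#'   type); ignored if `mad_k` is given.
#' @param mad_k MAD multiplier for threshold mode; `NULL` selects target
#'   mode.
#' @return A list: `dataset` (kept spectra), `removed_ids`, `scores` (data
#'   frame id, stage, score, removed).
#' @export
remove_outliers <- function(dataset, target_n = 100, mad_k = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  scores <- numeric(n_spectra(dataset))
  removed <- logical(n_spectra(dataset))
  for (cls in unique(dataset$labels)) {
    rows <- which(dataset$labels == cls)
    mu <- colMeans(dataset$matrix[rows, , drop = FALSE])
    sc <- rowSums(sweep(dataset$matrix[rows, , drop = FALSE], 2, mu)^2)
    scores[rows] <- sc
    if (is.null(mad_k)) {
      if (length(rows) < target_n) {
        stop("class '", cls, "' has ", length(rows),
             " spectra, fewer than target_n = ", target_n)
      }
      n_drop <- length(rows) - target_n
      if (n_drop > 0) {
        ord <- order(-sc, dataset$ids[rows])  # ties by id
        removed[rows[ord[seq_len(n_drop)]]] <- TRUE
      }
    } else {
      med <- stats::median(sc)
      madv <- stats::mad(sc)
      if (madv > 0) removed[rows[sc > med + mad_k * madv]] <- TRUE
    }
  }
  keep <- !removed
  list(dataset = subset_dataset(dataset, keep),
       removed_ids = dataset$ids[removed],
       scores = data.frame(id = dataset$ids, stage = dataset$labels,
                           score = scores, removed = removed,
                           stringsAsFactors = FALSE))
}
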
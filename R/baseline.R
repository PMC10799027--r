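# Iterative morphological baseline correction: greyscale opening (erosion
# then dilation over a window much wider than the Raman bands) estimates a
# lower envelope; convolution with a compactly supported mollifier smooths
# the envelope's corners; iterating on the pointwise minimum of the input
# and the current estimate lets the envelope relax under broad features
# until it stops changing.

# Pad a signal on both sides by `h` points of linear extrapolation, with
# the slope least-squares-fitted over the outermost `h + 1` points. Keeps
# sloped baselines (fluorescence ramps) from being clipped at the spectrum
# ends by the morphological window.
pad_linear <- function(y, h) {
  n <- length(y)
  m <- min(max(h + 1L, 5L), n)
  idx <- seq_len(m)
  slope_l <- stats::cov(idx, y[idx]) / stats::var(idx)
  slope_r <- stats::cov(idx, y[seq.int(n - m + 1L, n)]) / stats::var(idx)
  c(y[1] - slope_l * rev(seq_len(h)), y, y[n] + slope_r * seq_len(h))
}

# Running min/max over a centred window of half-width `halfw` points on a
# linearly extrapolated extension. Greedy doubling over window spans:
# O(n log halfw) in vectorized pmin/pmax calls.
run_extreme <- function(y_padded, halfw, fun) {
  L <- 2L * halfw + 1L
  f <- y_padded
  len <- 1L
  while (len < L) {
    s <- min(len, L - len)
    m <- length(f)
    f <- fun(f[seq_len(m - s)], f[seq.int(s + 1L, m)])
    len <- len + s
  }
  f
}

morph_opening <- function(y, halfw) {
  er <- run_extreme(pad_linear(y, 2L * halfw), halfw, pmin)
  run_extreme(er, halfw, pmax)
}

# Compactly supported smooth bump kernel exp(-1/(1-u^2)) on (-1, 1).
mollifier_kernel <- function(width) {
  width <- as.integer(width)
  if (width %% 2 == 0) width <- width + 1L
  u <- seq(-1, 1, length.out = width + 2L)[2:(width + 1L)]
  k <- exp(-1 / (1 - u^2))
  k / sum(k)
}

mollify <- function(y, width) {
  k <- mollifier_kernel(width)
  h <- (length(k) - 1L) %/% 2L
  padded <- pad_linear(y, h)
  as.numeric(stats::filter(padded, k, sides = 2))[(h + 1L):(h + length(y))]
}

#' Morphological baseline correction
#'
#' Estimates a smooth fluorescence-like baseline by iterated morphological
#' opening (erosion/dilation with half-width `w` points) followed by
#' mollifier smoothing, and subtracts it. The window should be much wider
#' than the Raman bands so peaks are excluded from the baseline estimate;
#' the mollifier rounds the piecewise-flat opening. Iteration stops when
#' the baseline changes by less than `tol` (sup norm) or after `max_iter`
#' passes, in which case the best iterate is returned with
#' `converged = FALSE`.
#'
#' `corrected + baseline` reconstructs the input to machine precision, and
#' the baseline never exceeds the input (it is clipped pointwise as the
#' final step).
#'
#' @param spectrum A [raman_spectrum()] or numeric vector.
#' @param w Structuring-element half-width in points (default 101).
#' @param mollifier_width Mollifier kernel width in points (default 21).
#' @param max_iter Maximum iterations (default 50).
#' @param tol Convergence tolerance on the baseline (default 1e-6).
#' @return A list: `corrected` (same type as input), `baseline` (numeric),
#'   `iterations`, `converged`.
#' @export
baseline_correct <- function(spectrum, w = 101, mollifier_width = 21,
                             max_iter = 50, tol = 1e-6) {
  stopifnot(w >= 1, mollifier_width > 0, max_iter >= 1)
  is_spec <- inherits(spectrum, "raman_spectrum")
  y <- if (is_spec) spectrum$intensity else as.numeric(spectrum)
  halfw <- as.integer(w)

  cur <- y
  est <- mollify(morph_opening(cur, halfw), mollifier_width)
  converged <- FALSE
  iter <- 1L
  while (iter < max_iter) {
    cur <- pmin(y, est)
    new_est <- mollify(morph_opening(cur, halfw), mollifier_width)
    delta <- max(abs(new_est - est))
    est <- new_est
    iter <- iter + 1L
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  baseline <- pmin(est, y)  # never above the signal
  corrected_vals <- y - baseline
  corrected <- if (is_spec) {
    raman_spectrum(spectrum$wavenumber, corrected_vals,
                   id = spectrum$meta$id, stage = spectrum$meta$stage,
                   window = spectrum$meta$window,
                   calibration_shift = spectrum$meta$calibration_shift)
  } else corrected_vals
  list(corrected = corrected, baseline = baseline,
       iterations = iter, converged = converged)
}

#' Baseline-correct every spectrum in a dataset
#'
#' @param dataset A [spectral_dataset()].
#' @inheritParams baseline_correct
#' @return A list: `dataset` (corrected), `baselines` (matrix, one row per
#'   spectrum), `converged` (logical per spectrum).
#' @export
baseline_correct_dataset <- function(dataset, w = 101, mollifier_width = 21,
                                     max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  out <- dataset$matrix
  bas <- dataset$matrix
  conv <- logical(n_spectra(dataset))
  for (i in seq_len(n_spectra(dataset))) {
    res <- baseline_correct(dataset$matrix[i, ], w, mollifier_width,
                            max_iter, tol)
    out[i, ] <- res$corrected
    bas[i, ] <- res$baseline
    conv[i] <- res$converged
  }
  list(dataset = spectral_dataset(dataset$grid, out, dataset$labels,
                                  dataset$ids),
       baselines = bas, converged = conv)
}
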
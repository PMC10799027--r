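# Synthetic single-cell Raman spectra for six oesophageal cell lines:
# HET-1A (healthy squamous), CP-A..CP-D (Barrett's, non-dysplastic through
# severe dysplasia), OE19 (adenocarcinoma). Spectra are a stage-weighted
# band sum plus fluorescence baseline, PDMS interferent, multiplicative
# scatter and additive noise.

#' Default disease-stage labels, healthy to cancer
#' @return Character vector of the six stage labels in progression order.
#' @export
default_stages <- function() {
  c("HET-1A", "CP-A", "CP-B", "CP-C", "CP-D", "OE19")
}

# Progression score per stage: adjacent dysplastic stages sit close together
# while the carcinoma line sits far from all of them, so that
# healthy-vs-cancer separation is large and adjacent-dysplasia separation is
# small. Magnitudes are package conventions, not measured values.
stage_progression <- function(stages = default_stages()) {
  scores <- c("HET-1A" = 0, "CP-A" = 0.30, "CP-B" = 0.38, "CP-C" = 0.46,
              "CP-D" = 0.55, "OE19" = 1.00)
  if (!all(stages %in% names(scores))) {
    stop("no default progression score for stage(s): ",
         paste(setdiff(stages, names(scores)), collapse = ", "))
  }
  scores[stages]
}

#' Default Raman band table for the six cell lines
#'
#' Band centers follow the bands of interest in oesophageal single-cell
#' spectra: tryptophan 880, phenylalanine/tryptophan shoulder 1009, DNA
#' PO2- backbone 1089, tyrosine 1171, Amide III 1250, collagen 1320, CH2
#' deformation 1450, cytochrome c 1583, tyrosine/tryptophan ring 1610,
#' Amide I 1656, and the high-wavenumber CH3 stretches 2881 and 2980 cm^-1.
#' Each band carries a per-stage multiplier; DNA, tryptophan, CH3/lipid and
#' related bands increase monotonically from HET-1A to OE19, reflecting
#' rising nucleic-acid and protein content with disease progression, while
#' the cytochrome c band decreases. Multiplier magnitudes are configurable
#' defaults, not measured fold changes.
#'
#' @param stages Stage labels; default [default_stages()].
#' @param shape Line-shape for every band: `"pseudo_voigt"` (default,
#'   50/50 Gaussian/Lorentzian mix), `"gaussian"` or `"lorentzian"`.
#' @return A data frame with one row per band: `center`, `width` (FWHM,
#'   cm^-1), `base_amplitude`, `shape`, `assignment`, `trend` (signed
#'   progression slope) and one `mult.<stage>` column per stage.
#' @export
default_band_table <- function(stages = default_stages(),
                               shape = "pseudo_voigt") {
  bands <- data.frame(
    center = c(880, 1009, 1089, 1171, 1250, 1320,
               1450, 1583, 1610, 1656, 2881, 2980),
    width = c(18, 12, 20, 14, 30, 26, 22, 16, 14, 28, 40, 35),
    base_amplitude = c(0.30, 0.50, 0.40, 0.25, 0.45, 0.35,
                       0.60, 0.30, 0.25, 1.00, 0.90, 0.60),
    shape = shape,
    assignment = c("tryptophan", "phenylalanine/tryptophan shoulder",
                   "DNA PO2- backbone", "tyrosine", "Amide III",
                   "collagen", "CH2 deformation (lipid)", "cytochrome c",
                   "tyrosine/tryptophan ring", "Amide I",
                   "CH3 stretch (protein/lipid)",
                   "CH3 stretch (protein/lipid)"),
    # signed slope of the stage multiplier along the progression score
    trend = c(0.50, 0.60, 0.80, 0.40, 0.20, 0.30,
              0.30, -0.30, 0.40, 0.00, 0.50, 0.50),
    stringsAsFactors = FALSE
  )
  prog <- stage_progression(stages)
  for (s in stages) {
    bands[[paste0("mult.", s)]] <- pmax(0, 1 + bands$trend * prog[[s]])
  }
  validate_band_table(bands, stages)
  bands
}

validate_band_table <- function(bands, stages) {
  stopifnot(is.data.frame(bands), nrow(bands) >= 1)
  if (any(bands$center < 300 | bands$center > 3200)) {
    stop("band centers must lie within the instrument range 300-3200 cm^-1")
  }
  if (any(bands$width <= 0)) stop("band widths (FWHM) must be positive")
  if (any(bands$base_amplitude < 0)) stop("band amplitudes must be >= 0")
  cols <- paste0("mult.", stages)
  missing <- setdiff(cols, names(bands))
  if (length(missing)) {
    stop("band table lacks stage multiplier column(s): ",
         paste(missing, collapse = ", "))
  }
  for (cc in cols) {
    if (any(bands[[cc]] < 0)) stop("stage multipliers must be >= 0")
  }
  invisible(bands)
}

#' Generator configuration
#'
#' Bundles the synthetic-dataset settings: stage labels, replicates per
#' stage, wavenumber grid (two acquisition windows generated contiguously
#' on one grid; membership is metadata), and the noise model.
#'
#' @param stages Stage labels.
#' @param n_per_stage Spectra per stage (>= 1).
#' @param grid_step Grid spacing in cm^-1 (default 1).
#' @param grid_range Overall range, default `c(300, 3200)` covering the
#'   300-1800 and 1800-3200 cm^-1 acquisition windows.
#' @param window_boundary Wavenumber separating the two windows (1800).
#' @param baseline_scale Scale of the random cubic fluorescence baseline
#'   (intensity units; 0 disables).
#' @param scatter_sd Lognormal sd of the per-cell multiplicative scatter
#'   factor (0 disables).
#' @param amp_sd Lognormal sd of per-cell, per-band amplitude heterogeneity
#'   (0 disables).
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param pdms_weight_range Range of the per-cell PDMS interferent weight;
#'   `c(0, 0)` disables the interferent.
#' @param seed Root seed; per-spectrum substreams are derived from it by
#'   (stage index, replicate index), so any subset of the dataset is
#'   reproducible independently.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(stages = default_stages(), n_per_stage = 100,
                             grid_step = 1, grid_range = c(300, 3200),
                             window_boundary = 1800,
                             baseline_scale = 0.2, scatter_sd = 0.1,
                             amp_sd = 0.1, noise_sd = 0.01,
                             pdms_weight_range = c(0.1, 0.5), seed = 1) {
  stopifnot(n_per_stage >= 1, grid_step > 0, baseline_scale >= 0,
            scatter_sd >= 0, amp_sd >= 0, noise_sd >= 0,
            length(pdms_weight_range) == 2,
            all(pdms_weight_range >= 0),
            diff(pdms_weight_range) >= 0)
  structure(
    list(stages = stages, n_per_stage = as.integer(n_per_stage),
         grid = seq(grid_range[1], grid_range[2], by = grid_step),
         window_boundary = window_boundary,
         baseline_scale = baseline_scale, scatter_sd = scatter_sd,
         amp_sd = amp_sd, noise_sd = noise_sd,
         pdms_weight_range = pdms_weight_range, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Evaluate one band's unit-height line shape on the grid.
band_shape <- function(nu, center, fwhm, shape) {
  g <- exp(-4 * log(2) * ((nu - center) / fwhm)^2)
  l <- 1 / (1 + 4 * ((nu - center) / fwhm)^2)
  switch(shape,
         gaussian = g,
         lorentzian = l,
         pseudo_voigt = 0.5 * g + 0.5 * l,
         stop("unknown band shape: ", shape))
}

#' Noise-free class mean profile for one stage
#'
#' The deterministic band sum `sum_b amp_b * mult_b(stage) * shape_b(nu)`
#' that a spectrum of that stage fluctuates around (before baseline, PDMS,
#' scatter and noise).
#'
#' @param stage Stage label.
#' @param bands Band table, e.g. [default_band_table()].
#' @param grid Wavenumber grid.
#' @return Numeric intensity vector on `grid`.
#' @export
band_profile <- function(stage, bands, grid) {
  col <- paste0("mult.", stage)
  if (!col %in% names(bands)) {
    stop("band table has no multipliers for stage '", stage, "'")
  }
  y <- numeric(length(grid))
  for (b in seq_len(nrow(bands))) {
    y <- y + bands$base_amplitude[b] * bands[[col]][b] *
      band_shape(grid, bands$center[b], bands$width[b], bands$shape[b])
  }
  y
}

#' Synthetic PDMS interferent reference spectrum
#'
#' A smooth, positive, deterministic stand-in for the polydimethylsiloxane
#' chip background, built from a small fixed set of broad bands at the
#' characteristic PDMS positions (488, 708, 1262, 1412, 2907 cm^-1). It is
#' defined pointwise, so restricting the grid restricts the output; the
#' same spectrum is used to contaminate generated data and as the EMSC
#' interferent column.
#'
#' @param grid Wavenumber grid (cm^-1).
#' @return A [raman_spectrum()] with id `"pdms-synthetic"`.
#' @export
pdms_reference <- function(grid) {
  centers <- c(488, 708, 1262, 1412, 2907)
  widths <- c(60, 45, 40, 40, 70)
  amps <- c(0.8, 0.6, 0.35, 0.3, 1.0)
  y <- numeric(length(grid))
  for (b in seq_along(centers)) {
    y <- y + amps[b] * band_shape(grid, centers[b], widths[b], "gaussian")
  }
  raman_spectrum(grid, y, id = "pdms-synthetic", stage = NA_character_)
}

# Deterministic per-spectrum substream seed from (root, stage idx, replicate).
substream_seed <- function(root, stage_idx, replicate) {
  as.integer((as.double(root) * 100003 + stage_idx * 7919 + replicate) %%
               2147483647)
}

# Runs code under a given seed, then restores the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate one synthetic single-cell spectrum
#'
#' The model is
#' `I(nu) = m * sum_b h_b * amp_b * mult_b(stage) * shape_b(nu)
#'          + baseline(nu) + g * pdms(nu) + eps(nu)`
#' with per-cell multiplicative scatter `m` (lognormal around 1), per-band
#' lognormal heterogeneity `h_b`, a random cubic fluorescence-like
#' baseline, a per-cell PDMS weight `g`, and additive Gaussian noise.
#'
#' @param stage Stage label; must be one of `config$stages`.
#' @param bands Band table.
#' @param config A [generator_config()].
#' @param seed Substream seed for this spectrum (all stochastic draws come
#'   from it).
#' @param id Spectrum id.
#' @return A [raman_spectrum()] whose ground-truth draws (`m`, `g`,
#'   baseline coefficients) are attached as attribute `"truth"`.
#' @export
generate_spectrum <- function(stage, bands = default_band_table(),
                              config = generator_config(), seed = 1,
                              id = paste0(stage, "-1")) {
  if (!stage %in% config$stages) {
    stop("unknown stage '", stage, "'; configured stages: ",
         paste(config$stages, collapse = ", "))
  }
  grid <- config$grid
  col <- paste0("mult.", stage)
  draws <- with_seed(seed, {
    list(
      m = if (config$scatter_sd > 0)
        stats::rlnorm(1, 0, config$scatter_sd) else 1,
      h = if (config$amp_sd > 0)
        stats::rlnorm(nrow(bands), 0, config$amp_sd) else
          rep(1, nrow(bands)),
      bcoef = if (config$baseline_scale > 0)
        config$baseline_scale * stats::runif(4) else numeric(4),
      g = if (diff(config$pdms_weight_range) > 0)
        stats::runif(1, config$pdms_weight_range[1],
                     config$pdms_weight_range[2]) else
          config$pdms_weight_range[1],
      eps = if (config$noise_sd > 0)
        stats::rnorm(length(grid), 0, config$noise_sd) else
          numeric(length(grid))
    )
  })
  signal <- numeric(length(grid))
  for (b in seq_len(nrow(bands))) {
    signal <- signal + draws$h[b] * bands$base_amplitude[b] *
      bands[[col]][b] *
      band_shape(grid, bands$center[b], bands$width[b], bands$shape[b])
  }
  x <- (grid - min(grid)) / (max(grid) - min(grid))
  baseline <- draws$bcoef[1] + draws$bcoef[2] * x +
    draws$bcoef[3] * x^2 + draws$bcoef[4] * x^3
  pdms <- pdms_reference(grid)$intensity
  intensity <- draws$m * signal + baseline + draws$g * pdms + draws$eps
  out <- raman_spectrum(
    grid, intensity, id = id, stage = stage,
    window = ifelse(grid <= config$window_boundary, "low", "high"))
  attr(out, "truth") <- list(m = draws$m, g = draws$g,
                             baseline_coef = draws$bcoef, seed = seed)
  out
}

#' Generate a full labelled synthetic dataset
#'
#' `n_per_stage` spectra per stage on the configured grid, with a
#' ground-truth record (per-spectrum scatter factor, PDMS weight, baseline
#' coefficients, substream seed) enabling recovery tests. Bit-reproducible
#' for a fixed `config$seed`; each spectrum's substream is derived from
#' (stage index, replicate index), so the dataset is invariant to
#' generation order.
#'
#' @param config A [generator_config()].
#' @param bands Band table; default [default_band_table()] on
#'   `config$stages`.
#' @return A list with elements `dataset` (a [spectral_dataset()]) and
#'   `truth` (a data frame: id, stage, m, g, b0..b3, seed).
#' @export
generate_dataset <- function(config = generator_config(),
                             bands = default_band_table(config$stages)) {
  validate_band_table(bands, config$stages)
  n_total <- length(config$stages) * config$n_per_stage
  mat <- matrix(NA_real_, nrow = n_total, ncol = length(config$grid))
  ids <- character(n_total); labs <- character(n_total)
  truth <- vector("list", n_total)
  row <- 0L
  for (si in seq_along(config$stages)) {
    stage <- config$stages[si]
    for (r in seq_len(config$n_per_stage)) {
      row <- row + 1L
      sseed <- substream_seed(config$seed, si, r)
      sp <- generate_spectrum(stage, bands, config, seed = sseed,
                              id = sprintf("%s-%03d", stage, r))
      mat[row, ] <- sp$intensity
      ids[row] <- sp$meta$id
      labs[row] <- stage
      tr <- attr(sp, "truth")
      truth[[row]] <- data.frame(
        id = sp$meta$id, stage = stage, m = tr$m, g = tr$g,
        b0 = tr$baseline_coef[1], b1 = tr$baseline_coef[2],
        b2 = tr$baseline_coef[3], b3 = tr$baseline_coef[4],
        seed = tr$seed, stringsAsFactors = FALSE)
    }
  }
  list(dataset = spectral_dataset(config$grid, mat, labs, ids),
       truth = do.call(rbind, truth))
}
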
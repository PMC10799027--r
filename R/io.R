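# Reading, writing, calibration and assembly of spectra.
# File dialect: two numeric columns (wavenumber, intensity), comma or
# whitespace delimited, optional single header line.

#' Read a two-column spectrum file
#'
#' Auto-detects comma vs whitespace delimiting and tolerates one header
#' line. Rejects non-numeric rows, non-finite values and non-monotone axes
#' with errors naming the offending row.
#'
#' @param path Path to a text/CSV file with columns (wavenumber, intensity).
#' @param id Spectrum id to attach; defaults to the file name.
#' @param stage Optional stage label to attach.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, id = NULL, stage = NA_character_) {
  if (!file.exists(path)) stop("no such spectrum file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty spectrum file: ", path)
  sep <- if (grepl(",", lines[[1]]) ||
             (length(lines) > 1 && grepl(",", lines[[2]]))) "," else ""
  parse_row <- function(ln) {
    parts <- if (identical(sep, ",")) strsplit(ln, ",")[[1]] else
      strsplit(trimws(ln), "[[:space:]]+")[[1]]
    trimws(parts)
  }
  first <- parse_row(lines[[1]])
  start <- 1L
  if (length(first) >= 2 &&
      any(is.na(suppressWarnings(as.numeric(first[1:2]))))) {
    start <- 2L  # header line
  }
  body <- lines[seq.int(start, length(lines))]
  if (length(body) < 2) stop("spectrum file has fewer than 2 data rows: ", path)
  wn <- numeric(length(body)); it <- numeric(length(body))
  for (j in seq_along(body)) {
    parts <- parse_row(body[[j]])
    if (length(parts) != 2) {
      stop("row ", j + start - 1L, " of ", path, " does not have 2 columns")
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals) || any(!is.finite(vals))) {
      stop("non-numeric or non-finite value at row ", j + start - 1L,
           " of ", path)
    }
    wn[j] <- vals[1]; it[j] <- vals[2]
  }
  d <- diff(wn)
  if (any(d <= 0)) {
    stop("wavenumber axis not strictly increasing in ", path,
         "; first offending row ", which(d <= 0)[1] + start)
  }
  raman_spectrum(wn, it, id = id %||% basename(path), stage = stage)
}

#' Write a spectrum to a two-column CSV file
#'
#' Values are written with 17 significant digits so that
#' `read_spectrum(write_spectrum(x))` round-trips to full double precision.
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  lines <- c("wavenumber,intensity",
             sprintf("%.17g,%.17g", spectrum$wavenumber, spectrum$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Calibrate a spectrum's wavenumber axis to the silicon reference band
#'
#' Shifts the whole axis by `520.5 - measured_si_peak` cm^-1 so the
#' measured silicon band lands on its reference position. Calibration is a
#' pure axis translation: intensities are untouched. Shifts larger than
#' 10 cm^-1 are suspect and raise a warning but are still applied.
#'
#' @param spectrum A [raman_spectrum()].
#' @param measured_si_peak Measured position of the Si band (cm^-1), > 0.
#' @param reference Reference Si band position; default 520.5 cm^-1.
#' @return The calibrated spectrum, with the applied shift recorded in
#'   `meta$calibration_shift`.
#' @export
calibrate_wavenumber <- function(spectrum, measured_si_peak,
                                 reference = 520.5) {
  stopifnot(inherits(spectrum, "raman_spectrum"), measured_si_peak > 0)
  shift <- reference - measured_si_peak
  if (abs(shift) > 10) {
    warning(sprintf(
      "suspect calibration: |shift| = %.2f cm^-1 exceeds 10 cm^-1 (applied anyway)",
      abs(shift)))
  }
  out <- raman_spectrum(spectrum$wavenumber + shift, spectrum$intensity,
                        id = spectrum$meta$id, stage = spectrum$meta$stage,
                        window = spectrum$meta$window,
                        calibration_shift =
                          spectrum$meta$calibration_shift + shift)
  out
}

#' Resample spectra onto a common wavenumber grid
#'
#' Linear interpolation onto `grid`; grid points outside a spectrum's
#' support are an error (no extrapolation, ever — silent edge extrapolation
#' would corrupt downstream EMSC fits).
#'
#' @param spectra A list of [raman_spectrum()] objects.
#' @param grid Target wavenumber grid (strictly increasing).
#' @param labels Optional stage labels (default: taken from each spectrum's
#'   metadata).
#' @return A [spectral_dataset()].
#' @export
to_common_grid <- function(spectra, grid, labels = NULL) {
  stopifnot(length(spectra) >= 1)
  grid <- as.numeric(grid)
  mat <- matrix(NA_real_, nrow = length(spectra), ncol = length(grid))
  ids <- character(length(spectra))
  labs <- character(length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    stopifnot(inherits(s, "raman_spectrum"))
    if (min(grid) < min(s$wavenumber) - 1e-9 ||
        max(grid) > max(s$wavenumber) + 1e-9) {
      stop("spectrum '", s$meta$id, "' (", min(s$wavenumber), "-",
           max(s$wavenumber), " cm^-1) does not cover the target grid (",
           min(grid), "-", max(grid), " cm^-1); refusing to extrapolate")
    }
    mat[i, ] <- stats::approx(s$wavenumber, s$intensity, xout = grid,
                              method = "linear", rule = 1)$y
    ids[i] <- s$meta$id
    labs[i] <- if (is.null(labels)) s$meta$stage %||% NA_character_ else
      labels[[i]]
  }
  spectral_dataset(grid, mat, labs, ids)
}

#' Merge the low- and high-wavenumber acquisition windows
#'
#' Joins two spectra acquired over adjacent windows (e.g. 300-1800 and
#' 1800-3200 cm^-1) into one spectrum with a strictly increasing axis. If
#' the windows share the boundary grid point, the mean of the two boundary
#' intensities is used; a gap or an overlap beyond `tol` is an error.
#'
#' @param low Spectrum covering the lower window.
#' @param high Spectrum covering the upper window.
#' @param tol Maximum allowed gap/overlap at the junction (cm^-1).
#' @return A merged [raman_spectrum()].
#' @export
merge_windows <- function(low, high, tol = 5) {
  stopifnot(inherits(low, "raman_spectrum"), inherits(high, "raman_spectrum"))
  lo_end <- low$wavenumber[length(low$wavenumber)]
  hi_start <- high$wavenumber[1]
  if (hi_start - lo_end > tol) {
    stop(sprintf("gap of %.2f cm^-1 between windows exceeds tolerance %.2f",
                 hi_start - lo_end, tol))
  }
  if (lo_end - hi_start > tol) {
    stop(sprintf(
      "windows overlap by %.2f cm^-1, more than tolerance %.2f",
      lo_end - hi_start, tol))
  }
  if (abs(hi_start - lo_end) < 1e-8) {
    # shared boundary point: average its two intensities
    n_lo <- length(low$wavenumber)
    wn <- c(low$wavenumber[-n_lo], hi_start, high$wavenumber[-1])
    it <- c(low$intensity[-n_lo],
            mean(c(low$intensity[n_lo], high$intensity[1])),
            high$intensity[-1])
  } else {
    wn <- c(low$wavenumber, high$wavenumber)
    it <- c(low$intensity, high$intensity)
    if (any(diff(wn) <= 0)) stop("merged axis not strictly increasing")
  }
  raman_spectrum(wn, it, id = low$meta$id, stage = low$meta$stage,
                 window = c(rep("low", sum(wn <= lo_end + 1e-9)),
                            rep("high", sum(wn > lo_end + 1e-9))),
                 calibration_shift = low$meta$calibration_shift)
}

#' Write a dataset as one wide CSV
#'
#' First column `wavenumber`, then one column per spectrum (named by id).
#'
#' @param dataset A [spectral_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(wavenumber = dataset$grid, t(dataset$matrix),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide-CSV dataset written by [write_dataset_csv()]
#'
#' @param path Path to the wide CSV.
#' @param labels Stage label per spectrum column, or a manifest data frame
#'   with columns `id` and `stage`.
#' @return A [spectral_dataset()].
#' @export
read_dataset_csv <- function(path, labels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  grid <- df[[1]]
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  ids <- colnames(df)[-1]
  labs <- rep(NA_character_, length(ids))
  if (is.data.frame(labels)) {
    labs <- labels$stage[match(ids, labels$id)]
  } else if (!is.null(labels)) {
    labs <- labels
  }
  spectral_dataset(grid, mat, labs, ids)
}

#' Write a dataset to a directory of per-spectrum files plus a manifest
#'
#' One two-column CSV per spectrum and a `manifest.csv` (id, stage, path),
#' the layout the file-input mode of the pipeline consumes.
#'
#' @param dataset A [spectral_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset_files <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(dataset$ids, ".csv"))
  for (i in seq_len(n_spectra(dataset))) {
    write_spectrum(get_spectrum(dataset, i), paths[i])
  }
  manifest <- data.frame(id = dataset$ids, stage = dataset$labels,
                         path = paths, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset from a manifest of per-spectrum files
#'
#' @param manifest_path Path to a `manifest.csv` with columns id, stage,
#'   path (paths relative to the manifest's directory or absolute).
#' @param grid Optional target grid; defaults to the first spectrum's axis.
#' @return A [spectral_dataset()].
#' @export
read_dataset_files <- function(manifest_path, grid = NULL) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  paths <- ifelse(file.exists(manifest$path), manifest$path,
                  file.path(base, basename(manifest$path)))
  spectra <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    spectra[[i]] <- read_spectrum(paths[i], id = manifest$id[i],
                                  stage = manifest$stage[i])
  }
  if (is.null(grid)) grid <- spectra[[1]]$wavenumber
  to_common_grid(spectra, grid)
}
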
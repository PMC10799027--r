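test_that("spectrum construction enforces its invariants", {
  expect_error(raman_spectrum(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(raman_spectrum(1000, 1), "at least 2")
  expect_error(raman_spectrum(c(1000, 999, 1001), c(1, 2, 3)),
               "strictly increasing")
  expect_error(raman_spectrum(c(1000, 1001), c(1, NA)), "non-finite")
  expect_error(raman_spectrum(c(1000, 1001), c(1, Inf)), "non-finite")
})

test_that("write/read round-trips spectra to full precision", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(10:200, 1)
    sp <- raman_spectrum(sort(runif(n, 300, 3200)) + seq_len(n) * 1e-6,
                         rnorm(n), id = paste0("rt", rep))
    path <- withr::local_tempfile(fileext = ".csv")
    write_spectrum(sp, path)
    back <- read_spectrum(path)
    expect_identical(back$wavenumber, sp$wavenumber)
    expect_identical(back$intensity, sp$intensity)
  }
})

test_that("reader tolerates headers, detects delimiters, rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,intensity", "1000,1.5", "1001,2.5"), path)
  sp <- read_spectrum(path)
  expect_equal(sp$intensity, c(1.5, 2.5))

  writeLines(c("1000 1.5", "1001 2.5", "1002 3.0"), path)
  expect_equal(read_spectrum(path)$intensity, c(1.5, 2.5, 3))

  writeLines(c("1000,1.5", "1001,abc"), path)
  expect_error(read_spectrum(path), "row 2")

  writeLines(c("1000,1.5", "999,2.5", "1003,2.0"), path)
  expect_error(read_spectrum(path), "row 2")

  writeLines(c("1000,1.5", "1001,NaN"), path)
  expect_error(read_spectrum(path), "non-numeric or non-finite")
})

test_that("calibration is a pure axis translation with the Si reference", {
  sp <- tiny_spectrum()
  cal <- calibrate_wavenumber(sp, 521.0)
  expect_equal(cal$wavenumber, sp$wavenumber - 0.5)
  expect_identical(cal$intensity, sp$intensity)
  expect_equal(cal$meta$calibration_shift, -0.5)

  expect_equal(calibrate_wavenumber(sp, 520.5)$wavenumber, sp$wavenumber)

  expect_warning(flagged <- calibrate_wavenumber(sp, 509.0), "suspect")
  expect_equal(flagged$wavenumber, sp$wavenumber + 11.5)
})

test_that("resampling onto a common grid interpolates linearly, never extrapolates", {
  sp <- tiny_spectrum()
  ds <- to_common_grid(list(sp), sp$wavenumber)
  expect_equal(ds$matrix[1, ], sp$intensity)

  ramp <- raman_spectrum(seq(0, 10, 2), seq(0, 10, 2) * 3, id = "ramp")
  mid <- to_common_grid(list(ramp), seq(1, 9, 2))
  expect_equal(mid$matrix[1, ], seq(1, 9, 2) * 3)

  short <- raman_spectrum(seq(800, 1700), rep(1, 901), id = "short-one")
  expect_error(to_common_grid(list(short), seq(800, 1800)), "short-one")
})

test_that("acquisition windows merge with the mean rule at the boundary", {
  low <- raman_spectrum(seq(300, 1800, 100), rep(2, 16), id = "s1")
  high <- raman_spectrum(seq(1800, 3200, 100), rep(4, 15), id = "s1")
  merged <- merge_windows(low, high)
  expect_equal(length(merged$wavenumber), 16 + 15 - 1)
  expect_equal(merged$intensity[merged$wavenumber == 1800], 3)
  expect_true(all(diff(merged$wavenumber) > 0))

  far <- raman_spectrum(seq(1850, 3200, 50), rep(1, 28), id = "s1")
  expect_error(merge_windows(low, far), "gap")
  overlapping <- raman_spectrum(seq(1700, 3200, 50), rep(1, 31), id = "s1")
  expect_error(merge_windows(low, overlapping), "overlap")
})

test_that("wide-CSV and per-file dataset exports round-trip", {
  gen <- generate_dataset(generator_config(n_per_stage = 3, grid_step = 50,
                                           seed = 9))
  ds <- gen$dataset
  wide <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, wide)
  back <- read_dataset_csv(wide, labels = data.frame(id = ds$ids,
                                                     stage = ds$labels))
  expect_equal(unname(back$matrix), unname(ds$matrix), tolerance = 1e-12)
  expect_equal(back$labels, ds$labels)

  dir <- withr::local_tempdir()
  write_dataset_files(ds, dir)
  back2 <- read_dataset_files(file.path(dir, "manifest.csv"))
  expect_equal(unname(back2$matrix), unname(ds$matrix), tolerance = 1e-12)
  expect_equal(back2$labels, ds$labels)
})
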
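test_that("fitting the reference to itself is the identity", {
  grid <- seq(800, 1800, 2)
  r <- band_profile("HET-1A", default_band_table(), grid)
  fit <- fit_emsc(r, r, poly_order = 0, grid = grid)
  expect_equal(fit$b, 1, tolerance = 1e-10)
  expect_equal(fit$c, 0, tolerance = 1e-10)
  expect_equal(fit$corrected$intensity, r, tolerance = 1e-10)
  expect_false(fit$degenerate)
})

test_that("scale and interferent weight are recovered exactly on constructions", {
  grid <- seq(800, 1800, 2)
  r <- band_profile("CP-B", default_band_table(), grid)
  pdms <- pdms_reference(grid)$intensity

  s <- 2 * r + 0.5 * pdms
  fit <- fit_emsc(s, r, list(pdms), poly_order = 0, grid = grid)
  expect_equal(fit$b, 2, tolerance = 1e-8)
  expect_equal(fit$g, 0.5, tolerance = 1e-8)
  expect_equal(fit$corrected$intensity, r, tolerance = 1e-8)

  # b = 1.3 with a linear baseline on the internally rescaled axis
  x <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  s2 <- 1.3 * r + 0.2 - 0.1 * x + 0.7 * pdms
  fit2 <- fit_emsc(s2, r, list(pdms), poly_order = 1, grid = grid)
  expect_equal(fit2$b, 1.3, tolerance = 1e-8)
  expect_equal(fit2$c, c(0.2, -0.1), tolerance = 1e-8)
  expect_equal(fit2$g, 0.7, tolerance = 1e-8)
  expect_equal(fit2$corrected$intensity, r, tolerance = 1e-8)
})

test_that("correction is invariant to adding any modelled baseline or interferent", {
  set.seed(7)
  grid <- seq(800, 1800, 5)
  bands <- default_band_table()
  r <- band_profile("CP-C", bands, grid)
  pdms <- pdms_reference(grid)$intensity
  s <- 1.4 * r + rnorm(1)
  base_fit <- fit_emsc(s, r, list(pdms), poly_order = 2, grid = grid)
  x <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  for (i in 1:5) {
    extra <- rnorm(1) + rnorm(1) * x + rnorm(1) * x^2 + runif(1) * pdms
    fit <- fit_emsc(s + extra, r, list(pdms), poly_order = 2, grid = grid)
    expect_equal(fit$corrected$intensity, base_fit$corrected$intensity,
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient designs and degenerate scales error informatively", {
  grid <- seq(1000, 1100, 1)
  r <- rep(1, length(grid))  # constant reference collides with poly0
  expect_error(fit_emsc(rnorm(length(grid)), r, poly_order = 0, grid = grid),
               "rank deficient")
  r2 <- band_profile("OE19", default_band_table(), grid)
  expect_error(fit_emsc(0 * r2 + 5e-12 * r2, r2, poly_order = 0,
                        grid = grid, interferents = list()),
               "degenerate")
})

test_that("dataset correction uses the pre-correction mean and flags failures", {
  grid <- seq(800, 1800, 5)
  r <- band_profile("CP-A", default_band_table(), grid)
  mat <- rbind(r, r, r)
  ds <- spectral_dataset(grid, mat, rep("CP-A", 3), paste0("s", 1:3))
  res <- emsc_correct_dataset(ds, poly_order = 2)
  expect_equal(res$reference$intensity, r, tolerance = 1e-12)
  for (i in 1:3) {
    expect_equal(res$dataset$matrix[i, ], r, tolerance = 1e-8)
  }
  expect_equal(res$fits$b, rep(1, 3), tolerance = 1e-8)

  expect_error(emsc_correct_dataset(
    spectral_dataset(grid, mat[0, , drop = FALSE], character(0),
                     character(0))), "empty")
})

test_that("ground-truth PDMS weights are recovered from generated data", {
  # one cell line per dataset, as spectra are compiled in practice, so the
  # mean-spectrum reference shares the class band structure
  cfg <- generator_config(stages = "CP-A", n_per_stage = 60, grid_step = 5,
                          seed = 21)
  gen <- generate_dataset(cfg, default_band_table("CP-A"))
  pdms <- pdms_reference(gen$dataset$grid)
  # plant a known PDMS weight of 0.7 in one spectrum
  ds <- gen$dataset
  j <- 17
  g_target <- 0.7
  ds$matrix[j, ] <- ds$matrix[j, ] +
    (g_target - gen$truth$g[j]) * pdms_reference(ds$grid)$intensity
  g_true <- gen$truth$g
  g_true[j] <- g_target
  pdms <- pdms_reference(ds$grid)
  res <- emsc_correct_dataset(ds, list(pdms), poly_order = 3)
  # the mean-spectrum reference itself carries the average PDMS weight, so
  # the fitted interferent coefficient estimates g_i - b_i * mean(g);
  # undo that shift before comparing with the generator draw
  g_hat <- res$fits$g1[j] + res$fits$b[j] * mean(g_true)
  expect_lt(abs(g_hat - g_target) / g_target, 0.05)
})
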
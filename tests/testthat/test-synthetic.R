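test_that("default band table covers the expected bands and stage structure", {
  bands <- default_band_table()
  expect_gte(nrow(bands), 11)
  expect_true(all(c(880, 1009, 1089, 1171, 1450, 1583, 1610, 1656,
                    2881, 2980) %in% bands$center))
  amide1 <- bands[bands$center == 1656, ]
  expect_match(amide1$assignment, "Amide I")
  expect_true(any(bands$center >= 1310 & bands$center <= 1340 &
                    grepl("collagen", bands$assignment)))
  expect_true(any(grepl("Amide III", bands$assignment)))

  mult_cols <- grep("^mult\\.", names(bands), value = TRUE)
  expect_length(mult_cols, 6)

  # disease-progression trends: DNA, tryptophan and CH3 bands rise
  # monotonically from HET-1A to OE19
  stages <- default_stages()
  for (centre in c(1009, 1089, 2881, 2980, 1450)) {
    m <- as.numeric(bands[bands$center == centre, paste0("mult.", stages)])
    expect_true(all(diff(m) > 0), info = paste("band", centre))
  }
  m1089 <- bands[bands$center == 1089, ]
  expect_gt(m1089[["mult.OE19"]], m1089[["mult.HET-1A"]])
})

test_that("pdms reference is deterministic, positive and pointwise-defined", {
  grid <- seq(300, 3200, 1)
  a <- pdms_reference(grid)
  b <- pdms_reference(grid)
  expect_identical(a$intensity, b$intensity)
  expect_true(all(a$intensity >= 0))

  sub <- grid[grid >= 800 & grid <= 1800]
  expect_identical(pdms_reference(sub)$intensity,
                   a$intensity[grid >= 800 & grid <= 1800])
})

test_that("noise-free spectra equal the analytic band sum", {
  cfg <- generator_config(n_per_stage = 1, grid_step = 2,
                          baseline_scale = 0, scatter_sd = 0, amp_sd = 0,
                          noise_sd = 0, pdms_weight_range = c(0, 0))
  bands <- default_band_table()
  for (stage in c("HET-1A", "OE19")) {
    sp <- generate_spectrum(stage, bands, cfg, seed = 1)
    expect_equal(sp$intensity, band_profile(stage, bands, cfg$grid),
                 tolerance = 1e-12)
  }
  # stage ordering at the DNA band under default multipliers
  het <- generate_spectrum("HET-1A", bands, cfg, seed = 1)
  oe <- generate_spectrum("OE19", bands, cfg, seed = 1)
  at <- which.min(abs(cfg$grid - 1089))
  expect_lt(het$intensity[at], oe$intensity[at])
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- generator_config(n_per_stage = 4, grid_step = 10, seed = 42)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$dataset$matrix, b$dataset$matrix)
  expect_identical(a$truth, b$truth)

  s1 <- generate_spectrum("CP-B", config = cfg, seed = 42)
  s2 <- generate_spectrum("CP-B", config = cfg, seed = 42)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("label marginals match the configuration exactly", {
  cfg <- generator_config(n_per_stage = 7, grid_step = 50, seed = 2)
  ds <- generate_dataset(cfg)$dataset
  expect_equal(n_spectra(ds), 6 * 7)
  expect_true(all(table(ds$labels) == 7))
  expect_false(anyDuplicated(ds$ids) > 0)
})

test_that("unknown stages are rejected by name", {
  cfg <- generator_config(n_per_stage = 1, grid_step = 50)
  expect_error(generate_spectrum("HeLa", config = cfg), "HeLa")
})

test_that("monotone multipliers order the noise-free class means at affected bands", {
  cfg <- generator_config(n_per_stage = 1, grid_step = 1,
                          baseline_scale = 0, scatter_sd = 0, amp_sd = 0,
                          noise_sd = 0, pdms_weight_range = c(0, 0))
  bands <- default_band_table()
  profiles <- sapply(default_stages(), band_profile, bands = bands,
                     grid = cfg$grid)
  for (centre in c(1009, 1089, 2881, 2980)) {
    at <- which(cfg$grid == centre)
    expect_true(all(diff(profiles[at, ]) > 0), info = paste("band", centre))
  }
})

test_that("ground-truth record enables coefficient recovery bookkeeping", {
  cfg <- generator_config(n_per_stage = 3, grid_step = 20, seed = 5)
  gen <- generate_dataset(cfg)
  expect_equal(nrow(gen$truth), n_spectra(gen$dataset))
  expect_identical(gen$truth$id, gen$dataset$ids)
  expect_true(all(gen$truth$g >= cfg$pdms_weight_range[1] &
                    gen$truth$g <= cfg$pdms_weight_range[2]))
  expect_true(all(gen$truth$m > 0))
})
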
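# Shared fixtures: all synthetic, built in code.

# A short deterministic spectrum for I/O and arithmetic tests.
tiny_spectrum <- function(n = 50, id = "tiny") {
  wn <- seq(1000, 1000 + (n - 1) * 2, by = 2)
  raman_spectrum(wn, sin(wn / 50) + 2, id = id, stage = "HET-1A")
}

# Band table for a custom two-class design (stages "A", "B"); class B
# scales each band by 1 + delta * |trend|.
two_class_bands <- function(delta = 0.05) {
  b <- default_band_table()
  b <- b[, c("center", "width", "base_amplitude", "shape", "assignment",
             "trend")]
  b[["mult.A"]] <- 1
  b[["mult.B"]] <- 1 + delta * abs(b$trend)
  b
}

# Noise-only two-class generator config on a fingerprint-only grid.
two_class_config <- function(seed, n_per_stage = 300, grid_step = 20,
                             noise_sd = 0.02) {
  generator_config(stages = c("A", "B"), n_per_stage = n_per_stage,
                   grid_step = grid_step, grid_range = c(800, 1800),
                   baseline_scale = 0, scatter_sd = 0, amp_sd = 0,
                   pdms_weight_range = c(0, 0), noise_sd = noise_sd,
                   seed = seed)
}

# Small labelled Gaussian-cloud dataset for classifier tests.
gaussian_clouds <- function(n_per_class = 12, d = 6, sep = 6, seed = 42,
                            classes = c("a", "b", "c")) {
  set.seed(seed)
  mats <- lapply(seq_along(classes), function(k) {
    centre <- rep(0, d)
    centre[k] <- sep
    sweep(matrix(rnorm(n_per_class * d), n_per_class, d), 2, centre, `+`)
  })
  x <- do.call(rbind, mats)
  list(x = x, labels = rep(classes, each = n_per_class))
}
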
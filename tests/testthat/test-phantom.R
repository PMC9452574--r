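test_that("design table is the full factorial product", {
  sp <- make_specimens(2, 2, seed = 1)
  d <- build_design_table(sp, wavelengths = c(700, 800),
                          grey_levels = c(8, 16, 32),
                          reconstructions = study_reconstructions(),
                          balance = TRUE)
  expect_equal(nrow(d), 4 * 2 * 3 * 2)

  d1 <- build_design_table(sp[1, , drop = FALSE], wavelengths = 800,
                           grey_levels = 8, reconstructions = "backprojection",
                           balance = FALSE)
  expect_equal(nrow(d1), 1)
  expect_error(build_design_table(sp, wavelengths = integer(0)),
               "non-empty")
})

test_that("balancing removes a reproducible surplus specimen", {
  sp <- make_specimens(10, 11, seed = 5)
  d1 <- build_design_table(sp, seed = 9)
  d2 <- build_design_table(sp, seed = 9)
  expect_identical(attr(d1, "removed"), attr(d2, "removed"))
  expect_length(attr(d1, "removed"), 1)
  expect_match(attr(d1, "removed"), "luminal")
  counts <- table(unique(d1[, c("specimen_id", "tumour_model")])$tumour_model)
  expect_equal(as.integer(counts), c(10L, 10L))
  expect_equal(nrow(d1), 10 * 2 * 9 * 6 * 2)
})

test_that("specimen simulation is seeded, sized and model-shaped", {
  cfg <- phantom_config()
  sp <- make_specimens(3, 3, cfg, seed = 2)
  sim1 <- simulate_specimen(sp[1, ], cfg, seed = 4)
  sim2 <- simulate_specimen(sp[1, ], cfg, seed = 4)
  expect_identical(sim1$volume$values, sim2$volume$values)

  # volume close to target; mask one connected component
  n <- sum(sim1$mask$mask)
  expect_lt(abs(n - sp$target_voi_voxels[1]) / sp$target_voi_voxels[1], 0.25)
  expect_silent(voi_mask(sim1$mask$mask, check_connected = TRUE))

  skew <- function(x) {
    mu <- mean(x); mean((x - mu)^3) / mean((x - mu)^2)^1.5
  }
  for (seed in c(4, 11)) {
    b <- simulate_specimen(sp[1, ], cfg, seed)
    l <- simulate_specimen(sp[4, ], cfg, seed)
    expect_gt(skew(voi_values(b$volume, b$mask)), 0.5)
    expect_lt(abs(skew(voi_values(l$volume, l$mask))), 0.3)
  }

  big <- sp[1, ]; big$target_voi_voxels <- 1e6L
  expect_error(simulate_specimen(big, cfg, 1), "capacity")
})

test_that("basal volumes are larger and more spread than luminal", {
  cfg <- phantom_config()
  sp <- do.call(rbind, lapply(1:10, function(s)
    make_specimens(10, 10, cfg, seed = s)))
  vb <- sp$target_voi_voxels[sp$tumour_model == "basal"]
  vl <- sp$target_voi_voxels[sp$tumour_model == "luminal"]
  expect_gt(mean(vb), mean(vl))
  expect_gt(var(vb), var(vl))
})

test_that("wavelength contrast is isobestic at 800 nm and rank-preserving", {
  cfg <- phantom_config()
  expect_equal(wavelength_factor(800, "basal", cfg),
               wavelength_factor(800, "luminal", cfg))
  expect_error(wavelength_factor(600, "basal", cfg), "domain")

  sp <- make_specimens(1, 1, cfg, seed = 3)
  sim <- simulate_specimen(sp[1, ], cfg, seed = 3)
  x0 <- voi_values(sim$volume, sim$mask)
  for (wl in study_wavelengths()) {
    out <- apply_wavelength_contrast(sim$volume, sim$mask, wl, "basal", cfg)
    x1 <- voi_values(out, sim$mask)
    expect_identical(order(x1), order(x0))          # monotone map
    expect_equal(mean(x1),
                 mean(x0) * wavelength_factor(wl, "basal", cfg),
                 tolerance = 1e-12)                 # closed-form curve
  }
})

test_that("reconstruction surrogates shift first-order stats, not skewness", {
  cfg <- phantom_config()
  sp <- make_specimens(1, 1, cfg, seed = 8)
  sim <- simulate_specimen(sp[1, ], cfg, seed = 8)

  # identity limit
  cfg0 <- phantom_config(bp_noise_sd = 0, mb_smooth = 0, mb_gain = 1,
                         mb_offset = 0)
  for (rec in study_reconstructions()) {
    out <- apply_reconstruction_surrogate(sim$volume, rec, cfg0, seed = 1)
    expect_equal(out$values, sim$volume$values, tolerance = 1e-12)
  }

  # smoothing a constant volume leaves it constant (then affine)
  cv <- image_volume(array(2, c(6, 6, 4)))
  out <- apply_reconstruction_surrogate(cv, "model_based", cfg, seed = 1)
  expect_equal(max(out$values) - min(out$values), 0, tolerance = 1e-12)

  expect_error(apply_reconstruction_surrogate(cv, "fbp", cfg, 1), "unknown")

  skew <- function(x) {
    mu <- mean(x); mean((x - mu)^3) / mean((x - mu)^2)^1.5
  }
  x0 <- voi_values(sim$volume, sim$mask)
  gap <- 2 / sqrt(cfg$basal_shape)        # between-model skewness gap
  for (rec in study_reconstructions()) {
    out <- apply_reconstruction_surrogate(sim$volume, rec, cfg, seed = 5)
    x1 <- voi_values(out, sim$mask)
    expect_lt(abs(skew(x1) - skew(x0)), 0.3 * gap)
    expect_gt(abs(mean(x1) - mean(x0)), 0)          # first-order moved
  }
})

test_that("cohort generation enumerates files, rows and seeds deterministically", {
  cfg <- phantom_config()
  sp <- make_specimens(2, 2, cfg, seed = 6)
  co <- generate_cohort(sp, cfg, seed = 6)
  expect_equal(length(co$volumes), 4 * 9 * 2)
  expect_equal(nrow(co$design), 4 * 9 * 6 * 2)

  sp1 <- make_specimens(1, 1, cfg, seed = 6)
  co1 <- generate_cohort(sp1, cfg, seed = 6, balance = FALSE)
  expect_equal(length(co1$volumes), 2 * 9 * 2)
  expect_equal(nrow(co1$design), 2 * 9 * 6 * 2)

  co2 <- generate_cohort(sp, cfg, seed = 6)
  expect_identical(co$manifest, co2$manifest)
})

test_that("basal minus luminal skewness gap persists across cohort seeds", {
  cfg <- phantom_config()
  skew <- function(x) {
    mu <- mean(x); mean((x - mu)^3) / mean((x - mu)^2)^1.5
  }
  gaps <- vapply(1:5, function(seed) {
    sp <- make_specimens(3, 3, cfg, seed = seed)
    s <- vapply(seq_len(nrow(sp)), function(i) {
      sim <- simulate_specimen(sp[i, ], cfg, seed)
      skew(voi_values(sim$volume, sim$mask))
    }, numeric(1))
    mean(s[sp$tumour_model == "basal"]) -
      mean(s[sp$tumour_model == "luminal"])
  }, numeric(1))
  expect_true(all(gaps > 0))
})
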
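test_that("terrain generation is deterministic and leaves the caller's RNG alone", {
  cfg <- small_cfg()
  set.seed(123); before <- runif(1)
  d1 <- generate_terrain(cfg)
  d2 <- generate_terrain(cfg)
  expect_identical(d1$values, d2$values)
  set.seed(123)
  expect_identical(runif(1), before)
  # different seed, different surface
  d3 <- generate_terrain(small_cfg(seed = 8))
  expect_false(identical(d1$values, d3$values))
})

test_that("large roughness exponents flatten the terrain towards a constant", {
  v_mid <- var(as.vector(generate_terrain(small_cfg(terrain_roughness = 3))$values))
  v_big <- var(as.vector(generate_terrain(small_cfg(terrain_roughness = 12))$values))
  v_huge <- var(as.vector(generate_terrain(small_cfg(terrain_roughness = 40))$values))
  expect_lt(v_big, v_mid / 100)
  expect_lt(v_huge, 1e-6)
})

test_that("terrain is spatially autocorrelated: semivariance rises with lag", {
  dem <- generate_terrain(small_cfg())$values
  semivar <- function(m, lag) mean((m[, seq_len(ncol(m) - lag)] -
                                      m[, seq_len(ncol(m) - lag) + lag])^2) / 2
  sv <- vapply(c(1, 4, 16, 64), semivar, 0, m = dem)
  expect_true(all(diff(sv) > 0))
})

test_that("snow depth follows the stated deterministic form in the noise-free case", {
  cfg <- small_cfg(terrain_relief = 0, noise_sd = 0, snow_base = 100,
                   snow_east_gradient = 0)
  dem <- generate_terrain(cfg)    # flat: relief 0
  snow <- generate_snow(cfg, dem)
  expect_equal(snow$snow_depth$values,
               matrix(100, cfg$extent, cfg$extent))
  expect_equal(snow$snow_free_fine$values,
               matrix(0, cfg$extent, cfg$extent))   # 100 cm: all snow-covered

  # depth exactly at the threshold classifies snow-free
  cfg35 <- small_cfg(terrain_relief = 0, noise_sd = 0, snow_base = 35,
                     snow_east_gradient = 0)
  snow35 <- generate_snow(cfg35, generate_terrain(cfg35))
  expect_true(all(snow35$snow_free_fine$values == 1))
})

test_that("snow accumulates in depressions: depth correlates negatively with TPI", {
  cfg <- small_cfg()
  dem <- generate_terrain(cfg)
  snow <- generate_snow(cfg, dem)
  tp <- tpi(dem, window = 120)
  expect_lt(cor(as.vector(snow$snow_depth$values), as.vector(tp$values)), 0)
  expect_true(all(snow$snow_depth$values >= 0))     # truncated at zero
})

test_that("NDSI scenes are noisy monotone maps of snow cover, clipped to [-1, 1]", {
  cfg <- small_cfg()
  frac <- grid_create(matrix(runif(100), 10, 10), 0, 300, 30)
  noiseless <- generate_ndsi_scenes(small_cfg(ndsi_noise_sd = 0), frac)
  for (s in noiseless[-1]) expect_equal(s$values, noiseless[[1]]$values)
  # snowier cells have higher NDSI, so NDSI falls with snow-FREE fraction
  expect_lt(cor(as.vector(noiseless[[1]]$values), as.vector(frac$values)), -0.99)

  noisy <- generate_ndsi_scenes(small_cfg(ndsi_noise_sd = 0.5), frac)
  for (s in noisy) expect_true(all(s$values >= -1 & s$values <= 1))
})

test_that("the scene mean tracks true snow cover better than single scenes", {
  # Monte-Carlo over seeds: correlation with truth must improve on average
  wins <- 0L
  for (seed in 1:20) {
    frac <- with(list(), {
      set.seed(1000 + seed)
      grid_create(matrix(runif(64), 8, 8), 0, 240, 30)
    })
    scenes <- generate_ndsi_scenes(small_cfg(seed = seed, ndsi_noise_sd = 0.4),
                                   frac)
    m <- mean_scene(scenes)
    cor_mean <- abs(cor(as.vector(m$values), as.vector(frac$values)))
    cor_single <- vapply(scenes, function(s)
      abs(cor(as.vector(s$values), as.vector(frac$values))), 0)
    wins <- wins + (cor_mean > max(cor_single))
  }
  expect_gt(wins, 14)   # mean beats the best single scene in most replicates
})

test_that("track simulation is deterministic with strictly increasing 3-h timestamps", {
  cfg <- small_cfg()
  sf <- generate_snow(cfg, generate_terrain(cfg))$snow_free_fine
  t1 <- simulate_tracks(cfg, sf)
  t2 <- simulate_tracks(cfg, sf)
  expect_identical(t1, t2)
  expect_length(t1, cfg$n_animals)
  for (tr in t1) {
    dt <- diff(as.numeric(tr$timestamp))
    expect_true(all(dt == cfg$step_interval * 3600))
    # positions stay on the grid (reflection at boundaries)
    expect_true(all(tr$x >= sf$origin_x &
                      tr$x <= sf$origin_x + ncol(sf$values) * sf$cell))
    expect_true(all(tr$y <= sf$origin_y &
                      tr$y >= sf$origin_y - nrow(sf$values) * sf$cell))
  }
})

test_that("selection strength beta drives on-patch use relative to availability", {
  cfg0 <- small_cfg(seed = 11, beta_snowfree = 0, n_animals = 4L,
                    n_steps = 600L)
  sf <- generate_snow(cfg0, generate_terrain(cfg0))$snow_free_fine
  avail <- availability_fraction(sf)

  ov0 <- overlay_positions(simulate_tracks(cfg0, sf), sf)
  n0 <- ov0$used_on + ov0$used_off
  p0 <- ov0$used_on / n0
  se <- sqrt(avail * (1 - avail) / n0)
  expect_lt(abs(p0 - avail), 3 * se)   # neutral movement matches availability

  cfg2 <- small_cfg(seed = 11, beta_snowfree = 2, n_animals = 4L,
                    n_steps = 600L)
  ov2 <- overlay_positions(simulate_tracks(cfg2, sf), sf)
  expect_gt(ov2$used_on / (ov2$used_on + ov2$used_off), avail + 3 * se)
})

test_that("bundle generation ties all layers to one georeference and the stated truth", {
  cfg <- small_cfg()
  b <- generate_bundle(cfg)
  expect_s3_class(b, "snowsel_bundle")
  expect_true(grid_same_geo(b$dem, b$snow_depth))
  expect_true(grid_same_geo(b$dem, b$snow_free_fine))
  expect_true(grid_same_geo(b$snow_fraction_true, b$ndsi_scenes[[1]]))
  expect_true(grid_same_geo(b$snow_fraction_true, b$lichen))
  # binary layer is exactly the 35 cm rule applied to the depth layer
  expect_equal(b$snow_free_fine$values, (b$snow_depth$values <= 35) + 0)
  expect_equal(b$truth$beta_snowfree, cfg$beta_snowfree)
  expect_length(b$ndsi_scenes, cfg$n_scenes)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(extent = 301), "divisible")
  expect_error(synthetic_config(n_candidates = 1), "n_candidates")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
})
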
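#' Configuration for the synthetic landscape and track generator
#'
#' Builds a validated configuration for [generate_bundle()] and the individual
#' generators. Defaults emulate the study system the package is designed for:
#' an alpine plateau where wind strips snow from ridges (positive TPI) and
#' redistributes it into depressions, a west-to-east precipitation gradient,
#' a ~131 cm mean late-winter snowpack, six satellite scenes, and GPS collars
#' reporting every 3 hours.
#'
#' @param seed integer master seed; every generator is a pure function of
#'   (seed, cfg).
#' @param extent fine-grid width/height in cells (square grid); must be
#'   divisible by `coarse_factor`.
#' @param fine_cell fine cell size (m).
#' @param coarse_factor fine cells per coarse cell side (30: 1 m -> 30 m).
#' @param terrain_roughness spectral-decay exponent of the terrain noise;
#'   larger = smoother (power-law spectrum).
#' @param terrain_relief amplitude scale of the terrain (m).
#' @param snow_base baseline snow depth (cm).
#' @param snow_tpi_gain cm of extra depth per meter of negative TPI
#'   (depressions collect snow; ridges are scoured).
#' @param snow_east_gradient cm per km eastwards (negative = drier east).
#' @param noise_sd cellwise depth noise sd (cm).
#' @param n_scenes number of synthetic NDSI scenes.
#' @param ndsi_noise_sd per-scene NDSI noise sd (unitless).
#' @param n_animals,n_steps number of tracks and steps per track.
#' @param step_interval hours between positions.
#' @param beta_snowfree selection strength (log-odds) for snow-free cells in
#'   the movement model; 0 = no selection.
#' @param n_candidates candidate displacements evaluated per step (>= 2).
#' @param step_scale isotropic displacement scale (m) per 3-h step.
#' @return a `snowsel_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             extent = 900L,
                             fine_cell = 1,
                             coarse_factor = 30L,
                             terrain_roughness = 3,
                             terrain_relief = 7,
                             snow_base = 131,
                             snow_tpi_gain = 26,
                             snow_east_gradient = -40,
                             noise_sd = 8,
                             n_scenes = 6L,
                             ndsi_noise_sd = 0.08,
                             n_animals = 5L,
                             n_steps = 400L,
                             step_interval = 3,
                             beta_snowfree = 2,
                             n_candidates = 8L,
                             step_scale = 150) {
  cfg <- list(seed = as.integer(seed), extent = as.integer(extent),
              fine_cell = fine_cell, coarse_factor = as.integer(coarse_factor),
              terrain_roughness = terrain_roughness,
              terrain_relief = terrain_relief,
              snow_base = snow_base, snow_tpi_gain = snow_tpi_gain,
              snow_east_gradient = snow_east_gradient, noise_sd = noise_sd,
              n_scenes = as.integer(n_scenes), ndsi_noise_sd = ndsi_noise_sd,
              n_animals = as.integer(n_animals), n_steps = as.integer(n_steps),
              step_interval = step_interval, beta_snowfree = beta_snowfree,
              n_candidates = as.integer(n_candidates), step_scale = step_scale)
  if (cfg$extent <= 0 || cfg$extent %% cfg$coarse_factor != 0)
    stop("`extent` must be positive and divisible by `coarse_factor`")
  for (p in c("terrain_relief", "noise_sd", "ndsi_noise_sd", "step_scale"))
    if (cfg[[p]] < 0) stop("`", p, "` must be >= 0")
  if (cfg$n_candidates < 2) stop("`n_candidates` must be >= 2")
  if (cfg$n_scenes < 1) stop("`n_scenes` must be >= 1")
  class(cfg) <- "snowsel_config"
  cfg
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched, making generators pure functions of their seed.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stage-specific sub-seed, kept within 32-bit integer range.
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7L + stage * 1009L) %% 2147483647
}

#' Generate a spatially autocorrelated terrain surface
#'
#' Spectral (power-law) synthesis: complex white noise is shaped by
#' `(f / f0)^(-roughness/2)` in the frequency domain (f in cycles per domain,
#' `f0 = 0.5`) and transformed back. One exponent controls autocorrelation;
#' as `terrain_roughness` grows, all mode amplitudes shrink and the surface
#' tends to a constant. Amplitudes are scaled deterministically so that at
#' the reference exponent 3 the surface standard deviation equals
#' `terrain_relief`; the scale is a pure function of the configuration, so
#' realizations stay reproducible and the large-roughness limit is kept.
#'
#' @param cfg a [synthetic_config()].
#' @return DEM grid (m), `extent` x `extent`, reproducible from `cfg$seed`.
#' @export
generate_terrain <- function(cfg) {
  n <- cfg$extent
  with_seed(stage_seed(cfg$seed, 1L), {
    fr <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
    fmat <- sqrt(outer(fr^2, fr^2, `+`))
    w <- (fmat / 0.5)^(-cfg$terrain_roughness / 2)
    w[1, 1] <- 0
    # theoretical surface sd for reference-exponent weights; fixes the scale
    # without per-realization normalization
    w_ref <- (fmat / 0.5)^(-3 / 2)
    w_ref[1, 1] <- 0
    sd_ref <- sqrt(sum(w_ref^2)) / n
    noise <- matrix(stats::rnorm(n * n), n, n) +
      1i * matrix(stats::rnorm(n * n), n, n)
    z <- Re(stats::fft(noise * w, inverse = TRUE)) / n
    grid_create(z * cfg$terrain_relief / sd_ref, origin_x = 0,
                origin_y = n * cfg$fine_cell, cell = cfg$fine_cell)
  })
}

#' Generate a snow-depth field and its snow-free classification
#'
#' Depth = max(0, base + gain * (-TPI) + east_gradient * x_km + noise):
#' depressions (negative TPI) collect snow, ridges are scoured bare, and a
#' west-to-east gradient mimics declining precipitation. The binary layer
#' applies the 35 cm snow-free rule via [classify_snow_free_fine()].
#' Wind redistribution acts on broader terrain forms than the 30 m analysis
#' window, so the generating TPI uses its own (larger) window; whole ridge
#' crests then blow bare, producing spatially coherent snow-free patches.
#'
#' @param cfg a [synthetic_config()].
#' @param dem fine DEM grid from [generate_terrain()].
#' @param tpi_window TPI window (m) driving snow redistribution.
#' @return list with `snow_depth` (cm) and `snow_free_fine` (binary) grids.
#' @export
generate_snow <- function(cfg, dem, tpi_window = 120) {
  tpi_fine <- tpi(dem, window = tpi_window)
  x_km <- matrix(grid_x_centers(dem) / 1000, nrow(dem$values),
                 ncol(dem$values), byrow = TRUE)
  depth <- with_seed(stage_seed(cfg$seed, 2L), {
    cfg$snow_base + cfg$snow_tpi_gain * (-tpi_fine$values) +
      cfg$snow_east_gradient * x_km +
      matrix(stats::rnorm(length(x_km), sd = cfg$noise_sd), nrow(x_km))
  })
  depth <- grid_like(dem, pmax(depth, 0))
  list(snow_depth = depth, snow_free_fine = classify_snow_free_fine(depth))
}

#' Generate noisy NDSI scenes coherent with true snow cover
#'
#' Each scene is one monotone map of the snow-covered fraction
#' (`ndsi = -0.2 + 1.0 * (1 - snow_free_fraction)`, so more snow means a
#' higher index) plus independent Gaussian noise, clipped to \[-1, 1\].
#' Averaging scenes should therefore track the truth better than any single
#' noisy scene.
#'
#' @param cfg a [synthetic_config()].
#' @param snow_fraction_true coarse grid of true snow-FREE fractions in
#'   \[0, 1\].
#' @return list of `cfg$n_scenes` NDSI grids.
#' @export
generate_ndsi_scenes <- function(cfg, snow_fraction_true) {
  y <- snow_fraction_true$values
  if (any(y < 0 | y > 1, na.rm = TRUE))
    stop("snow fractions must lie in [0, 1]")
  base <- -0.2 + 1.0 * (1 - y)
  with_seed(stage_seed(cfg$seed, 3L), {
    lapply(seq_len(cfg$n_scenes), function(i) {
      v <- base + matrix(stats::rnorm(length(y), sd = cfg$ndsi_noise_sd),
                         nrow(y))
      v <- pmin(pmax(v, -1), 1)
      v[is.na(y)] <- NA_real_
      grid_like(snow_fraction_true, v)
    })
  })
}

#' Generate a lichen-cover raster on the coarse grid
#'
#' Lichen heath develops on exposed, snow-poor ridges: cover increases with
#' coarse-scale TPI, plus noise, clipped to \[0, 100\] %.
#'
#' @param cfg a [synthetic_config()].
#' @param tpi_coarse coarse-grid TPI (m).
#' @return lichen cover grid (%).
#' @export
generate_lichen <- function(cfg, tpi_coarse) {
  with_seed(stage_seed(cfg$seed, 4L), {
    v <- 25 + 20 * tpi_coarse$values +
      matrix(stats::rnorm(length(tpi_coarse$values), sd = 8),
             nrow(tpi_coarse$values))
    grid_like(tpi_coarse, pmin(pmax(v, 0), 100))
  })
}

#' Simulate GPS tracks with known preference for snow-free cells
#'
#' Discrete-choice movement model: at each 3-h step an animal draws
#' `n_candidates` isotropic Gaussian displacement proposals (sd `step_scale`
#' per axis) and picks candidate j with probability proportional to
#' `exp(beta_snowfree * I[snow-free at j])`. Proposals landing outside the
#' grid are reflected at the boundary, which keeps availability constant
#' without absorbing animals.
#'
#' @param cfg a [synthetic_config()].
#' @param snow_free_fine fine binary snow-free grid.
#' @param start ISO start time (UTC) of the first position.
#' @return list of tracks; each is a data.frame with `animal_id`, `timestamp`
#'   (POSIXct UTC, strictly increasing, `step_interval` hours apart), `x`, `y`.
#' @export
simulate_tracks <- function(cfg, snow_free_fine,
                            start = as.POSIXct("2015-01-01 00:00:00",
                                               tz = "UTC")) {
  g <- snow_free_fine
  xmin <- g$origin_x; xmax <- g$origin_x + ncol(g$values) * g$cell
  ymin <- g$origin_y - nrow(g$values) * g$cell; ymax <- g$origin_y
  reflect <- function(p, lo, hi) {
    span <- hi - lo
    p <- (p - lo) %% (2 * span)
    lo + ifelse(p > span, 2 * span - p, p)
  }
  with_seed(stage_seed(cfg$seed, 5L), {
    lapply(seq_len(cfg$n_animals), function(a) {
      x <- numeric(cfg$n_steps + 1L)
      y <- numeric(cfg$n_steps + 1L)
      x[1] <- stats::runif(1, xmin, xmax)
      y[1] <- stats::runif(1, ymin, ymax)
      for (s in seq_len(cfg$n_steps)) {
        cx <- x[s] + stats::rnorm(cfg$n_candidates, sd = cfg$step_scale)
        cy <- y[s] + stats::rnorm(cfg$n_candidates, sd = cfg$step_scale)
        cx <- reflect(cx, xmin, xmax)
        cy <- reflect(cy, ymin, ymax)
        sf <- grid_extract(g, cx, cy)
        sf[is.na(sf)] <- 0
        wgt <- exp(cfg$beta_snowfree * sf)
        j <- sample.int(cfg$n_candidates, 1L, prob = wgt)
        x[s + 1L] <- cx[j]
        y[s + 1L] <- cy[j]
      }
      data.frame(
        animal_id = sprintf("animal_%02d", a),
        timestamp = start + (seq_len(cfg$n_steps + 1L) - 1L) *
          cfg$step_interval * 3600,
        x = x, y = y
      )
    })
  })
}

#' Generate a complete synthetic bundle
#'
#' Runs every generator in order and returns all layers plus the generating
#' truth: DEM, snow depth, binary snow-free layer (35 cm rule), true coarse
#' snow-free fraction, NDSI scenes, coarse TPI, lichen cover, and tracks.
#'
#' @param cfg a [synthetic_config()].
#' @return a `snowsel_bundle` list.
#' @export
generate_bundle <- function(cfg) {
  dem <- generate_terrain(cfg)
  snow <- generate_snow(cfg, dem)
  frac_true <- aggregate_fraction(snow$snow_free_fine, cfg$coarse_factor)
  ndsi_scenes <- generate_ndsi_scenes(cfg, frac_true)
  tpi_fine <- tpi(dem, window = 30)
  tpi_coarse <- grid_create(
    block_reduce(tpi_fine$values, cfg$coarse_factor, mean),
    dem$origin_x, dem$origin_y, dem$cell * cfg$coarse_factor)
  lichen <- generate_lichen(cfg, tpi_coarse)
  tracks <- simulate_tracks(cfg, snow$snow_free_fine)
  structure(list(
    cfg = cfg, dem = dem, snow_depth = snow$snow_depth,
    snow_free_fine = snow$snow_free_fine, snow_fraction_true = frac_true,
    ndsi_scenes = ndsi_scenes, tpi_fine = tpi_fine, tpi_coarse = tpi_coarse,
    lichen = lichen, tracks = tracks,
    truth = list(beta_snowfree = cfg$beta_snowfree,
                 snow_free_threshold_cm = 35,
                 availability_fraction_fine =
                   mean(snow$snow_free_fine$values, na.rm = TRUE))
  ), class = "snowsel_bundle")
}
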
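#' Classify fine-grid cells as snow-free by a depth threshold
#'
#' A fine (1 m) cell counts as snow-free when its snow depth is at or below
#' the threshold; the default 35 cm is the depth at which a laser-intensity
#' image renders a cell "black" (bare ground).
#'
#' @param depth grid of snow depths (cm), non-negative or `NA`.
#' @param threshold depth (cm) at or below which a cell is snow-free.
#' @return binary grid: 1 = snow-free (depth <= threshold), 0 = snow-covered;
#'   `NA` propagated.
#' @export
classify_snow_free_fine <- function(depth, threshold = 35) {
  v <- depth$values
  if (any(v < 0, na.rm = TRUE)) stop("negative snow depths are not allowed")
  grid_like(depth, (v <= threshold) + 0)
}

#' Normalized-Difference Snow Index
#'
#' NDSI = (green - SWIR) / (green + SWIR); high over snow because snow is
#' bright in the green band and dark in shortwave infrared.
#'
#' @param green,swir reflectance grids (non-negative), same georeference.
#' @return NDSI grid in \[-1, 1\]; cells where both bands are 0 become `NA`.
#' @export
ndsi <- function(green, swir) {
  stop_if_misaligned(green, swir, what = "NDSI input bands")
  g <- green$values; s <- swir$values
  if (any(g < 0, na.rm = TRUE) || any(s < 0, na.rm = TRUE))
    stop("reflectances must be non-negative")
  denom <- g + s
  out <- (g - s) / denom
  out[denom == 0] <- NA_real_
  grid_like(green, out)
}

#' Cellwise mean across scenes, skipping missing cells
#'
#' @param scenes non-empty list of aligned grids (e.g. per-scene NDSI).
#' @return grid of cellwise means over non-`NA` scenes; all-`NA` cells stay `NA`.
#' @export
mean_scene <- function(scenes) {
  if (!length(scenes)) stop("at least one scene is required")
  for (s in scenes) stop_if_misaligned(scenes[[1]], s, what = "scenes")
  acc <- matrix(0, nrow(scenes[[1]]$values), ncol(scenes[[1]]$values))
  cnt <- acc
  for (s in scenes) {
    v <- s$values
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  grid_like(scenes[[1]], out)
}

# Summed-area table padded with a leading row/column of zeros, NA -> 0.
sat_pad <- function(m) {
  m[is.na(m)] <- 0
  rbind(0, cbind(0, t(apply(apply(m, 2, cumsum), 1, cumsum))))
}

# Sum of m over the window [r1..r2] x [c1..c2] for each cell, windows clipped
# to the grid. r1, r2, c1, c2 are matrices of row/col bounds.
sat_window_sum <- function(S, r1, r2, c1, c2) {
  nr <- nrow(S) - 1L
  idx <- function(r, c) S[cbind(as.vector(r), as.vector(c))]
  out <- idx(r2 + 1L, c2 + 1L) - idx(r1, c2 + 1L) -
    idx(r2 + 1L, c1) + idx(r1, c1)
  matrix(out, nrow = nrow(r1))
}

window_bounds <- function(nr, nc, h) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  list(r1 = pmax(r - h, 1L), r2 = pmin(r + h, nr),
       c1 = pmax(c - h, 1L), c2 = pmin(c + h, nc))
}

#' Topographic Position Index
#'
#' Each cell's elevation minus the mean elevation of its square moving-window
#' neighborhood: positive on ridges and knolls, negative in depressions.
#' Windows are truncated at grid edges (no padding with invented elevations).
#'
#' @param dem elevation grid (m).
#' @param window window size (m); the neighborhood half-width is
#'   `floor(window / (2 * cell))` cells, so 30 m on a 1 m grid gives a
#'   31 x 31 cell window.
#' @param exclude_center drop the focal cell from the neighborhood mean
#'   (default TRUE, the common convention).
#' @return TPI grid (m); `NA` where the DEM is `NA` or no neighbors exist.
#' @export
tpi <- function(dem, window = 30, exclude_center = TRUE) {
  h <- floor(window / (2 * dem$cell))
  if (h < 1) stop("TPI window must span at least 3 cells across")
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  b <- window_bounds(nr, nc, h)
  S <- sat_pad(v)
  Scnt <- sat_pad(!is.na(v) + 0)
  tot <- sat_window_sum(S, b$r1, b$r2, b$c1, b$c2)
  n <- sat_window_sum(Scnt, b$r1, b$r2, b$c1, b$c2)
  if (exclude_center) {
    v0 <- v; v0[is.na(v0)] <- 0
    tot <- tot - v0
    n <- n - !is.na(v)
  }
  out <- v - tot / n
  out[n == 0] <- NA_real_
  grid_like(dem, out)
}

#' Aggregate a fine binary grid to coarse snow-free fractions
#'
#' Each coarse cell nests exactly `factor` x `factor` fine cells; its value is
#' the fraction of valid fine cells equal to 1 (snow-free). Note the stored
#' convention is the snow-FREE fraction; the snow-covered fraction is its
#' complement `1 - x`.
#'
#' @param fine_binary fine binary grid (1 = snow-free).
#' @param factor fine cells per coarse cell side (e.g. 30 for 1 m -> 30 m).
#' @return snow-free-fraction grid on the coarse georeference; coarse cells
#'   with no valid fine cell are `NA`.
#' @export
aggregate_fraction <- function(fine_binary, factor) {
  v <- fine_binary$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% factor != 0 || nc %% factor != 0)
    stop("fine grid dimensions must be divisible by the aggregation factor")
  ones <- block_reduce(ifelse(is.na(v), 0, v), factor, sum)
  valid <- block_reduce((!is.na(v)) + 0, factor, sum)
  out <- ones / valid
  out[valid == 0] <- NA_real_
  grid_create(out, fine_binary$origin_x, fine_binary$origin_y,
              fine_binary$cell * factor)
}

# Block reduction of a matrix by an integer factor with a vectorized
# accumulator (sum or mean over factor^2 blocks).
block_reduce <- function(m, factor, fun = sum) {
  nr <- nrow(m); nc <- ncol(m)
  a <- array(m, dim = c(factor, nr / factor, nc))
  s <- apply(a, c(2, 3), fun)                 # collapse rows within block
  a2 <- array(t(s), dim = c(factor, nc / factor, nr / factor))
  t(apply(a2, c(2, 3), fun))
}

#' Slope and hillshade from a DEM
#'
#' Central-difference gradients (one-sided at edges); slope in degrees,
#' hillshade as standard illumination in \[0, 1\].
#'
#' @param dem elevation grid (m).
#' @param sun_azimuth sun azimuth, degrees clockwise from north.
#' @param sun_altitude sun altitude above the horizon, degrees.
#' @return list with `slope` (degrees) and `hillshade` (\[0, 1\]) grids.
#' @export
slope_hillshade <- function(dem, sun_azimuth = 315, sun_altitude = 45) {
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  gradient_1d <- function(m, along_cols) {
    if (along_cols) m <- t(m)
    n <- nrow(m)
    if (n == 1) return(if (along_cols) t(m * 0) else m * 0)
    d <- (rbind(m[2:n, , drop = FALSE], m[n, , drop = FALSE]) -
          rbind(m[1, , drop = FALSE], m[1:(n - 1), , drop = FALSE])) /
      c(1, rep(2, max(n - 2, 0)), 1)
    if (along_cols) t(d) else d
  }
  dz_drow <- gradient_1d(v, FALSE) / dem$cell    # towards south (row down)
  dz_dcol <- gradient_1d(v, TRUE) / dem$cell     # towards east
  dz_dx <- dz_dcol
  dz_dy <- -dz_drow                              # y increases northwards
  slope_rad <- atan(sqrt(dz_dx^2 + dz_dy^2))
  aspect <- atan2(dz_dx, dz_dy)                  # 0 = north, clockwise
  zen <- (90 - sun_altitude) * pi / 180
  az <- sun_azimuth * pi / 180
  hs <- cos(zen) * cos(slope_rad) +
    sin(zen) * sin(slope_rad) * cos(az - aspect)
  hs <- pmin(pmax(hs, 0), 1)
  list(slope = grid_like(dem, slope_rad * 180 / pi),
       hillshade = grid_like(dem, hs))
}
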
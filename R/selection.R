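#' Areal availability fraction of a binary mask
#'
#' Fraction of valid (non-`NA`) cells equal to 1 — the proportional-
#' availability ("random walk") null expectation for the share of positions
#' on mask cells.
#'
#' @param mask binary grid.
#' @return fraction in \[0, 1\].
#' @export
availability_fraction <- function(mask) {
  mean(mask$values == 1, na.rm = TRUE)
}

#' Overlay GPS positions on a binary mask
#'
#' Counts positions falling on mask = 1 vs mask = 0 cells. Positions outside
#' the grid extent (or on `NA` cells) are excluded and counted separately.
#'
#' @param tracks a track data.frame (`animal_id`, `timestamp`, `x`, `y`) or a
#'   list of them.
#' @param mask binary grid.
#' @return list: `used_on`, `used_off`, `n_excluded`.
#' @export
overlay_positions <- function(tracks, mask) {
  pts <- bind_tracks(tracks)
  v <- grid_extract(mask, pts$x, pts$y)
  if (all(is.na(v)))
    stop("all positions fall outside the mask extent")
  list(used_on = sum(v == 1, na.rm = TRUE),
       used_off = sum(v == 0, na.rm = TRUE),
       n_excluded = sum(is.na(v)))
}

bind_tracks <- function(tracks) {
  if (is.data.frame(tracks)) return(tracks)
  do.call(rbind, tracks)
}

#' Expected count under proportional availability
#'
#' @param n_used total number of positions.
#' @param availability_fraction areal fraction of the habitat class.
#' @return real-valued expected count (rounding is display-only).
#' @export
expected_under_proportional <- function(n_used, availability_fraction) {
  if (availability_fraction < 0 || availability_fraction > 1)
    stop("`availability_fraction` must lie in [0, 1]")
  n_used * availability_fraction
}

#' Odds ratio with Wald confidence interval for a 2x2 use-availability table
#'
#' OR = (used_on / used_off) / (avail_on / avail_off), with the 95% Wald CI
#' `exp(log(OR) +/- z * SE)`, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, and a
#' two-sided p-value from `z = log(OR) / SE`. Counts may be real-valued
#' (expected counts under the proportional null are used directly).
#'
#' @param used_on,used_off observed positions on/off the habitat class.
#' @param avail_on,avail_off availability counts (e.g. expected positions
#'   on/off under proportional use).
#' @param conf confidence level.
#' @param correction add 0.5 to every cell (Haldane-Anscombe) — required
#'   explicitly when any cell is 0, never applied silently.
#' @return a `snowsel_selection` list: `odds_ratio`, `ci_low`, `ci_high`,
#'   `se_log_or`, `p_value`, `conf`, and the (possibly corrected) table.
#' @export
odds_ratio <- function(used_on, used_off, avail_on, avail_off,
                       conf = 0.95, correction = FALSE) {
  cells <- c(used_on = used_on, used_off = used_off,
             avail_on = avail_on, avail_off = avail_off)
  if (any(cells < 0)) stop("table cells must be non-negative")
  if (any(cells == 0)) {
    if (!correction)
      stop("zero cell in the 2x2 table; re-run with `correction = TRUE` ",
           "to apply the Haldane-Anscombe +0.5 correction")
    cells <- cells + 0.5
  }
  or <- (cells["used_on"] / cells["used_off"]) /
    (cells["avail_on"] / cells["avail_off"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lor <- log(or)
  structure(list(
    odds_ratio = unname(or),
    ci_low = unname(exp(lor - z * se)),
    ci_high = unname(exp(lor + z * se)),
    se_log_or = unname(se),
    p_value = unname(2 * stats::pnorm(-abs(lor / se))),
    conf = conf,
    table = cells
  ), class = "snowsel_selection")
}

#' @export
print.snowsel_selection <- function(x, ...) {
  cat(sprintf("Odds ratio %.4g (%d%% CI %.4f-%.4f), p = %.3g\n",
              x$odds_ratio, round(100 * x$conf), x$ci_low, x$ci_high,
              x$p_value))
  invisible(x)
}

#' Selection against the proportional-availability null
#'
#' Builds the full 2x2 table from the observed on/off counts and the areal
#' availability fraction (availability cells are the expected on/off counts
#' for the same total), then computes the selection ratio and odds ratio.
#'
#' @param used_on,used_off observed counts.
#' @param availability_fraction areal fraction of the habitat class.
#' @param ... passed to [odds_ratio()].
#' @return a `snowsel_selection` with additional fields
#'   `availability_fraction`, `expected_on`, `ratio` (observed/expected) and
#'   `excess_pct` (`(ratio - 1) * 100`).
#' @export
selection_vs_availability <- function(used_on, used_off,
                                      availability_fraction, ...) {
  n <- used_on + used_off
  expected_on <- expected_under_proportional(n, availability_fraction)
  res <- odds_ratio(used_on, used_off, expected_on, n - expected_on, ...)
  res$availability_fraction <- availability_fraction
  res$expected_on <- expected_on
  res$ratio <- if (expected_on > 0) used_on / expected_on else NA_real_
  res$excess_pct <- (res$ratio - 1) * 100
  res
}

#' Sunrise and sunset from solar geometry
#'
#' Standard solar-position computation (declination and equation of time from
#' the day-angle Fourier expansion; hour angle at zenith 90.833 degrees, i.e.
#' including standard refraction and solar radius). Times are UTC.
#'
#' @param date a `Date` (or string coercible to one).
#' @param lat,lon latitude/longitude in degrees (lon positive east).
#' @return list: `sunrise`, `sunset` (POSIXct UTC), `day_length_h`, and
#'   `polar` (TRUE when the sun never rises or never sets; times are `NA`).
#' @export
solar_times <- function(date, lat, lon) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)   # fractional-year angle at solar noon
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- lat * pi / 180
  zen <- 90.833 * pi / 180
  cos_ha <- (cos(zen) - sin(latr) * sin(decl)) / (cos(latr) * cos(decl))
  if (!is.finite(cos_ha) || cos_ha > 1 || cos_ha < -1) {
    return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA),
                day_length_h = if (is.finite(cos_ha) && cos_ha < -1) 24 else 0,
                polar = TRUE))
  }
  ha <- acos(cos_ha) * 180 / pi
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  sunrise <- midnight + 60 * (720 - 4 * (lon + ha) - eqtime)
  sunset <- midnight + 60 * (720 - 4 * (lon - ha) - eqtime)
  list(sunrise = sunrise, sunset = sunset,
       day_length_h = as.numeric(difftime(sunset, sunrise, units = "hours")),
       polar = FALSE)
}

#' Classify a timestamp into a diel period
#'
#' Periods are anchored to the date's sunrise and sunset, half-open on the
#' right: morning \[sunrise-1h, sunrise+1h), day \[sunrise+1h, sunset-1h),
#' evening \[sunset-1h, sunset+1h), night the remainder; the four periods
#' tile the 24-h day exactly.
#'
#' @param timestamp POSIXct (UTC).
#' @param sunrise,sunset POSIXct (UTC) for the relevant date.
#' @return factor level in `c("day", "evening", "night", "morning")`.
#' @export
classify_diel <- function(timestamp, sunrise, sunset) {
  if (is.na(sunrise) || is.na(sunset)) stop("polar date: no sunrise/sunset")
  if (sunrise >= sunset) stop("sunrise must precede sunset")
  h <- 3600
  out <- ifelse(timestamp >= sunrise - h & timestamp < sunrise + h, "morning",
         ifelse(timestamp >= sunrise + h & timestamp < sunset - h, "day",
         ifelse(timestamp >= sunset - h & timestamp < sunset + h, "evening",
                "night")))
  factor(out, levels = c("day", "evening", "night", "morning"))
}

#' Per-diel-period selection against proportional availability
#'
#' Labels every position with its diel period (per-date sunrise/sunset at the
#' study coordinates), then computes per-period observed counts, expected
#' counts under proportional availability, selection ratios, excess-use
#' percentages and odds ratios.
#'
#' @param tracks track data.frame or list of them (timestamps UTC).
#' @param mask binary snow-free grid.
#' @param lat,lon study-area coordinates (degrees) used for solar times.
#' @param availability_fraction optional; defaults to
#'   [availability_fraction()] of `mask`.
#' @return data.frame with one row per period: `period`, `n`, `observed_on`,
#'   `expected_on`, `ratio`, `excess_pct`, `or`, `ci_low`, `ci_high`;
#'   positions on polar dates (no sunrise/sunset) are dropped with a warning.
#' @export
diel_selection <- function(tracks, mask, lat, lon,
                           availability_fraction = NULL) {
  pts <- bind_tracks(tracks)
  if (is.null(availability_fraction))
    availability_fraction <- availability_fraction(mask)
  dates <- as.Date(pts$timestamp, tz = "UTC")
  sol <- lapply(unique(dates), solar_times, lat = lat, lon = lon)
  names(sol) <- as.character(unique(dates))
  polar <- vapply(sol, `[[`, TRUE, "polar")
  keep <- !polar[as.character(dates)]
  if (any(!keep))
    warning(sum(!keep), " positions on polar dates dropped")
  pts <- pts[keep, , drop = FALSE]
  dates <- dates[keep]
  period <- factor(rep(NA_character_, nrow(pts)),
                   levels = c("day", "evening", "night", "morning"))
  for (d in unique(as.character(dates))) {
    rows <- which(as.character(dates) == d)
    period[rows] <- classify_diel(pts$timestamp[rows],
                                  sol[[d]]$sunrise, sol[[d]]$sunset)
  }
  on <- grid_extract(mask, pts$x, pts$y)
  res <- lapply(levels(period), function(p) {
    rows <- period == p & !is.na(on)
    n <- sum(rows)
    if (n == 0)
      return(data.frame(period = p, n = 0L, observed_on = NA_real_,
                        expected_on = NA_real_, ratio = NA_real_,
                        excess_pct = NA_real_, or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    obs <- sum(on[rows] == 1)
    sel <- selection_vs_availability(obs, n - obs, availability_fraction,
                                     correction = obs == 0 || obs == n)
    data.frame(period = p, n = n, observed_on = obs,
               expected_on = sel$expected_on, ratio = sel$ratio,
               excess_pct = sel$excess_pct, or = sel$odds_ratio,
               ci_low = sel$ci_low, ci_high = sel$ci_high)
  })
  do.call(rbind, res)
}
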
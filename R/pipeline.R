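#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: the synthetic-landscape
#' configuration (or pre-built bundle), snow-free thresholds, patch
#' connectivity, GPS snapping buffer, diel stratification, availability
#' sample size, and calibration controls.
#'
#' @param synthetic a [synthetic_config()] (used to generate the input
#'   bundle).
#' @param thresholds snow-free-fraction thresholds defining patch scenarios.
#' @param connectivity patch connectivity (4 or 8).
#' @param buffer GPS snapping radius (m).
#' @param diel compute per-diel-period selection?
#' @param lat,lon study coordinates (degrees) for solar times.
#' @param n_avail availability sample size for the RSPF design.
#' @param quota_per_bin calibration rows per 10% snow-fraction bin.
#' @param n_transects number of east-west reference transects emulated
#'   (fine-grid reference coverage is restricted to these bands).
#' @param include_lichen use the lichen-cover layer? When FALSE (layer
#'   unavailable), models containing LICHEN are skipped with a warning.
#' @param exclusions list of exclusion polygons (x, y matrices), or empty.
#' @param out_dir optional output directory for artifacts and the manifest.
#' @return a `snowsel_pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            thresholds = c(0.8, 0.5, 0.3),
                            connectivity = 8,
                            buffer = 5,
                            diel = TRUE,
                            lat = 60, lon = 7.5,
                            n_avail = 5000,
                            quota_per_bin = 40,
                            n_transects = 6,
                            include_lichen = TRUE,
                            exclusions = list(),
                            out_dir = NULL) {
  cfg <- list(synthetic = synthetic, thresholds = thresholds,
              connectivity = connectivity, buffer = buffer, diel = diel,
              lat = lat, lon = lon, n_avail = n_avail,
              quota_per_bin = quota_per_bin, n_transects = n_transects,
              include_lichen = include_lichen, exclusions = exclusions,
              out_dir = out_dir)
  stopifnot(all(thresholds > 0 & thresholds <= 1), connectivity %in% c(4, 8),
            buffer >= 0, n_avail >= 1, quota_per_bin >= 1, n_transects >= 1)
  class(cfg) <- "snowsel_pipeline_config"
  cfg
}

# Binary coarse grid marking emulated reference (transect) coverage:
# n_transects evenly spaced east-west bands.
transect_coverage <- function(coarse_template, n_transects, band_rows = 2L) {
  nr <- nrow(coarse_template$values)
  centers <- round(seq(1, nr, length.out = n_transects + 2))[2:(n_transects + 1)]
  v <- matrix(0, nr, ncol(coarse_template$values))
  for (ctr in centers) {
    rows <- max(1, ctr - band_rows %/% 2):min(nr, ctr + (band_rows - 1) %/% 2)
    v[rows, ] <- 1
  }
  grid_like(coarse_template, v)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic bundle
#'
#' Executes: landscape/track synthesis, NDSI averaging and terrain indices,
#' snow-fraction calibration (balanced sampling, repeated 5-fold CV, two-best
#' ensemble) and area-wide prediction, patch delineation and statistics per
#' threshold, selection analysis against proportional availability (overall
#' and per diel period), and RSPF model fitting with AIC ranking and
#' goodness-of-fit/collinearity diagnostics. When `cfg$out_dir` is set,
#' writes per-stage artifacts (ASCII grids, track CSV, patch GeoJSON, JSON
#' report) and a manifest (config, package version, seeds).
#'
#' @param cfg a [pipeline_config()].
#' @return a nested report list with sections `config_summary`, `synthetic`,
#'   `calibration`, `patches`, `selection`, `diel`, `rspf`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  scfg <- cfg$synthetic
  bundle <- run_stage("synthetic", generate_bundle(scfg))
  ndsi_mean <- run_stage("indices", mean_scene(bundle$ndsi_scenes))
  tpi_coarse <- bundle$tpi_coarse

  # --- calibration against the fine-grid reference within transect bands ---
  calib <- run_stage("calibration", {
    coverage <- transect_coverage(tpi_coarse, cfg$n_transects)
    cal <- make_calibration_set(ndsi_mean, tpi_coarse,
                                bundle$snow_fraction_true, coverage)
    cal_bal <- balanced_sample(cal, cfg$quota_per_bin,
                               seed = stage_seed(scfg$seed, 11L))
    ens <- fit_ensemble(cal_bal,
                        list(learner_pspline(), learner_gbstumps(),
                             learner_linear()),
                        seed = stage_seed(scfg$seed, 12L))
    list(coverage = coverage, data = cal_bal, ensemble = ens)
  })
  frac_pred <- run_stage("prediction",
                         predict_fraction(calib$ensemble, ndsi_mean,
                                          tpi_coarse))

  # --- patches per threshold scenario ---
  patches <- run_stage("patches", {
    lapply(stats::setNames(cfg$thresholds, paste0("t", cfg$thresholds * 100)),
           function(t) {
      mask <- threshold_mask(frac_pred, t)
      ps <- label_patches(mask, connectivity = cfg$connectivity)
      if (length(cfg$exclusions)) ps <- apply_exclusions(ps, cfg$exclusions)
      list(threshold = t, mask = mask, patches = ps,
           stats = patch_stats(ps),
           total_area_km2 = sum(ps$table$area_m2) / 1e6,
           availability_fraction = availability_fraction(mask))
    })
  })

  # --- selection vs proportional availability ---
  selection <- run_stage("selection", {
    lapply(patches, function(p) {
      ov <- overlay_positions(bundle$tracks, p$mask)
      sel <- selection_vs_availability(ov$used_on, ov$used_off,
                                       p$availability_fraction)
      list(threshold = p$threshold, used_on = ov$used_on,
           used_off = ov$used_off, n_excluded = ov$n_excluded,
           availability_fraction = p$availability_fraction,
           expected_on = sel$expected_on, ratio = sel$ratio,
           pct_on = 100 * ov$used_on / (ov$used_on + ov$used_off),
           odds_ratio = sel$odds_ratio, ci_low = sel$ci_low,
           ci_high = sel$ci_high, p_value = sel$p_value)
    })
  })

  diel <- if (cfg$diel) run_stage("diel", {
    lapply(patches, function(p)
      diel_selection(bundle$tracks, p$mask, cfg$lat, cfg$lon,
                     p$availability_fraction))
  }) else NULL

  # --- RSPF on the fine-grid design ---
  rspf <- run_stage("rspf", {
    mask30 <- threshold_mask(frac_pred, 0.3)
    dist_surface <- distance_to_snowfree(mask30,
                                         connectivity = cfg$connectivity)
    layers <- list(snow_depth = bundle$snow_depth, dem = bundle$dem,
                   tpi = bundle$tpi_fine, dist = dist_surface,
                   lichen = if (cfg$include_lichen) bundle$lichen)
    design <- build_design(bundle$tracks, layers, n_avail = cfg$n_avail,
                           seed = stage_seed(scfg$seed, 13L),
                           buffer = cfg$buffer)
    std <- standardize_design(design)
    have_lichen <- "LICHEN" %in% names(std$design)
    model_terms <- list(
      full = c("DIST", "SNOW", "XCOORD", "DEM2", "DEM", "TPI", "LICHEN",
               "SNOW:LICHEN"),
      no_tpi = c("DIST", "SNOW", "XCOORD", "DEM2", "DEM", "LICHEN",
                 "SNOW:LICHEN"),
      no_snow = c("DIST", "XCOORD", "DEM2", "DEM", "TPI", "LICHEN"),
      no_lichen = c("DIST", "SNOW", "XCOORD", "DEM2", "DEM", "TPI"),
      no_dist = c("SNOW", "XCOORD", "DEM2", "DEM", "TPI", "LICHEN",
                  "SNOW:LICHEN"),
      no_dem = c("DIST", "SNOW", "XCOORD", "TPI", "LICHEN", "SNOW:LICHEN"),
      no_xcoord = c("DIST", "SNOW", "DEM2", "DEM", "TPI", "LICHEN",
                    "SNOW:LICHEN")
    )
    if (!have_lichen) {
      drop <- vapply(model_terms, function(tt)
        any(grepl("LICHEN", tt)), TRUE)
      keep_names <- names(model_terms)[!drop]
      warning("lichen layer missing: skipping models ",
              paste(names(model_terms)[drop], collapse = ", "))
      model_terms <- lapply(model_terms[keep_names], identity)
    }
    fits <- lapply(model_terms, function(tt) fit_rspf(std$design, tt))
    ranking <- rank_models(fits)
    best <- fits[[ranking$model[1]]]
    vif_terms <- intersect(c("DIST", "SNOW", "XCOORD", "DEM", "TPI", "LICHEN"),
                           names(std$design))
    list(design_counts = attr(design, "counts"), standardization =
           list(means = std$means, sds = std$sds),
         fits = fits, ranking = ranking,
         best_model = ranking$model[1],
         hosmer_lemeshow = hosmer_lemeshow(best, std$design),
         vif = vif(std$design, vif_terms))
  })

  report <- list(
    config_summary = list(seed = scfg$seed, extent = scfg$extent,
                          coarse_factor = scfg$coarse_factor,
                          thresholds = cfg$thresholds,
                          beta_snowfree = scfg$beta_snowfree),
    synthetic = list(
      truth = bundle$truth,
      n_positions = sum(vapply(bundle$tracks, nrow, 0L)),
      snow_free_fine_fraction = bundle$truth$availability_fraction_fine),
    calibration = list(
      n_rows = nrow(calib$data),
      cv = calib$ensemble$cv,
      chosen = calib$ensemble$chosen,
      predictor_cor = calib$ensemble$predictor_cor,
      prediction_r2_vs_truth = {
        ok <- !is.na(frac_pred$values) & !is.na(bundle$snow_fraction_true$values)
        1 - sum((frac_pred$values[ok] -
                   bundle$snow_fraction_true$values[ok])^2) /
          sum((bundle$snow_fraction_true$values[ok] -
                 mean(bundle$snow_fraction_true$values[ok]))^2)
      }),
    patches = lapply(patches, function(p)
      list(threshold = p$threshold, n_patches = p$stats$n_patches,
           total_area_km2 = p$total_area_km2,
           availability_fraction = p$availability_fraction,
           area_median_m2 = p$stats$area_median_m2,
           nn_median_m = p$stats$nn_median_m,
           frac_within_100m = p$stats$frac_within_100m,
           excluded_pct = p$patches$excluded_pct)),
    selection = selection,
    diel = diel,
    rspf = rspf[setdiff(names(rspf), "fits")]
  )
  report$rspf$coefficients_best <-
    as.list(rspf$fits[[rspf$best_model]]$coefficients)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ascii_grid(bundle$dem, file.path(cfg$out_dir, "dem.asc"))
    write_ascii_grid(frac_pred, file.path(cfg$out_dir,
                                          "snow_free_fraction.asc"))
    write_tracks_csv(bundle$tracks, file.path(cfg$out_dir, "tracks.csv"))
    for (nm in names(patches))
      write_patches_geojson(patches[[nm]]$patches,
                            file.path(cfg$out_dir,
                                      paste0("patches_", nm, ".geojson")),
                            csv = file.path(cfg$out_dir,
                                            paste0("patches_", nm, ".csv")))
    write_report_json(report, file.path(cfg$out_dir, "report.json"))
    manifest <- list(
      package = "snowsel",
      version = as.character(utils::packageVersion("snowsel")),
      timestamp = strftime(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      seed = scfg$seed,
      config = cfg[setdiff(names(cfg), "out_dir")]
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, force = TRUE, pretty = TRUE)
  }
  report
}
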
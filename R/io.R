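#' Read and write GPS tracks as CSV
#'
#' Columns: `animal_id`, `timestamp` (ISO-8601 UTC), `x`, `y`. Reading
#' validates the schema and rejects non-increasing timestamps per animal,
#' reporting offending line numbers.
#'
#' @param path file path.
#' @param tracks track data.frame or list of per-animal data.frames.
#' @return `read_tracks_csv` returns one data.frame (POSIXct timestamps);
#'   `write_tracks_csv` returns `path` invisibly.
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  if (!all(need %in% names(d)))
    stop("track CSV must have columns: ", paste(need, collapse = ", "))
  ts <- as.POSIXct(rep(NA_real_, nrow(d)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M:%S")) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(d$timestamp[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(ts) | !is.finite(d$x) | !is.finite(d$y))
  if (length(bad))
    stop("malformed track rows at lines: ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  d$timestamp <- ts
  for (a in unique(d$animal_id)) {
    rows <- which(d$animal_id == a)
    dec <- rows[which(diff(as.numeric(ts[rows])) <= 0)]
    if (length(dec))
      stop("non-increasing timestamps for ", a, " at lines: ",
           paste(utils::head(dec + 2L, 10), collapse = ", "))
  }
  d
}

#' @rdname read_tracks_csv
#' @export
write_tracks_csv <- function(tracks, path) {
  d <- bind_tracks(tracks)
  d$timestamp <- strftime(d$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(d[, c("animal_id", "timestamp", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Export patches as GeoJSON
#'
#' Each patch becomes a MultiPolygon feature made of its cell squares, with
#' `id`, `n_cells` and `area_m2` properties; the attribute table is also
#' written as CSV alongside when `csv` is given.
#'
#' @param ps a `snowsel_patches`.
#' @param path output GeoJSON path.
#' @param csv optional path for the attribute table.
#' @return `path` invisibly.
#' @export
write_patches_geojson <- function(ps, path, csv = NULL) {
  lab <- ps$labels
  nr <- nrow(lab$values)
  feats <- lapply(seq_len(nrow(ps$table)), function(i) {
    idx <- which(lab$values == i)
    col <- (idx - 1L) %/% nr
    row <- (idx - 1L) %% nr
    x0 <- lab$origin_x + col * lab$cell
    y0 <- lab$origin_y - (row + 1) * lab$cell
    polys <- lapply(seq_along(idx), function(j) {
      xs <- x0[j] + c(0, lab$cell, lab$cell, 0, 0)
      ys <- y0[j] + c(0, 0, lab$cell, lab$cell, 0)
      list(Map(c, xs, ys))
    })
    list(type = "Feature",
         properties = list(id = ps$table$id[i],
                           n_cells = ps$table$n_cells[i],
                           area_m2 = ps$table$area_m2[i]),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv)) utils::write.csv(ps$table, csv, row.names = FALSE)
  invisible(path)
}

#' Read exclusion polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features; only outer
#' rings are used.
#'
#' @param path GeoJSON file.
#' @return list of two-column vertex matrices.
#' @export
read_polygons_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  feats <- if (!is.null(j$features)) j$features else list(j)
  out <- list()
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    ring_to_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    if (geom$type == "Polygon") {
      out <- c(out, list(ring_to_mat(geom$coordinates[[1]])))
    } else if (geom$type == "MultiPolygon") {
      out <- c(out, lapply(geom$coordinates, function(p) ring_to_mat(p[[1]])))
    } else stop("unsupported geometry type: ", geom$type)
  }
  out
}

#' Write an analysis report as JSON
#'
#' @param report named list (as from [run_pipeline()]).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}
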
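#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix plus a planar georeference.
#' The origin is the top-left corner of the grid in projected map units (m);
#' cell (i, j) (1-based row i counted downwards, column j rightwards) has its
#' center at `(origin_x + (j - 0.5) * cell, origin_y - (i - 0.5) * cell)`.
#' Missing data are `NA` in memory; file I/O maps them to a nodata sentinel.
#'
#' @param values numeric matrix (rows = north-to-south).
#' @param origin_x,origin_y map coordinates (m) of the top-left grid corner.
#' @param cell cell size (m), > 0.
#' @return an object of class `snowsel_grid`.
#' @export
grid_create <- function(values, origin_x = 0, origin_y = nrow(values) * cell,
                        cell = 1) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell) || length(cell) != 1L || !is.finite(cell) || cell <= 0)
    stop("`cell` must be a single positive number")
  structure(
    list(values = values, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), cell = as.numeric(cell)),
    class = "snowsel_grid"
  )
}

#' @export
print.snowsel_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<snowsel_grid> %d x %d cells, cell %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell, x$origin_x, x$origin_y))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.snowsel_grid <- function(x) dim(x$values)

is_grid <- function(x) inherits(x, "snowsel_grid")

#' Test whether two grids share the same georeference and shape
#'
#' @param a,b grids.
#' @param tol absolute tolerance on origin and cell size (m).
#' @return logical.
#' @export
grid_same_geo <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell - b$cell) < tol
}

stop_if_misaligned <- function(..., what = "grids") {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!grid_same_geo(gs[[1]], gs[[i]]))
      stop(sprintf("%s are not aligned (georeference or shape differs)", what))
  invisible(TRUE)
}

#' Replace the values of a grid, keeping its georeference
#' @param g grid template.
#' @param values matrix with the same dimensions.
#' @return grid.
#' @export
grid_like <- function(g, values) {
  if (!identical(dim(values), dim(g$values)))
    stop("replacement values have different dimensions")
  grid_create(values, g$origin_x, g$origin_y, g$cell)
}

#' Map-coordinate vectors of cell centers
#' @param g grid.
#' @return numeric vector of column-center x (resp. row-center y) coordinates.
#' @export
grid_x_centers <- function(g) g$origin_x + (seq_len(ncol(g$values)) - 0.5) * g$cell

#' @rdname grid_x_centers
#' @export
grid_y_centers <- function(g) g$origin_y - (seq_len(nrow(g$values)) - 0.5) * g$cell

#' Locate points on a grid
#'
#' Half-open cell convention: a point exactly on a shared vertical edge belongs
#' to the cell on the right; on a shared horizontal edge, to the cell below.
#'
#' @param g grid.
#' @param x,y point coordinates (map units).
#' @return data.frame with `row`, `col` (NA when outside the grid extent).
#' @export
grid_locate <- function(g, x, y) {
  col <- floor((x - g$origin_x) / g$cell) + 1
  row <- floor((g$origin_y - y) / g$cell) + 1
  bad <- col < 1 | col > ncol(g$values) | row < 1 | row > nrow(g$values) |
    !is.finite(col) | !is.finite(row)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Grid values at point locations
#' @param g grid.
#' @param x,y point coordinates.
#' @return numeric vector (NA outside the extent).
#' @export
grid_extract <- function(g, x, y) {
  rc <- grid_locate(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text headered raster format (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`, then rows north to south).
#'
#' @param path file path.
#' @param g grid to write.
#' @param nodata sentinel written for `NA` cells.
#' @return `read_ascii_grid` returns a grid; `write_ascii_grid` returns
#'   `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  head <- readLines(path, n = 6L)
  kv <- strsplit(trimws(head), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else NA_real_
  body <- scan(path, skip = 6L, quiet = TRUE)
  nr <- vals[["nrows"]]; nc <- vals[["ncols"]]
  if (length(body) != nr * nc)
    stop(sprintf("ASCII grid %s: expected %d values, found %d",
                 path, nr * nc, length(body)))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  grid_create(m,
              origin_x = vals[["xllcorner"]],
              origin_y = vals[["yllcorner"]] + nr * vals[["cellsize"]],
              cell = vals[["cellsize"]])
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - nr * g$cell),
    sprintf("cellsize %.10g", g$cell),
    sprintf("NODATA_value %g", nodata)
  )
  rows <- apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
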
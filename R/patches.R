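#' Binary snow-free mask from a fraction grid
#'
#' A coarse cell counts as snow-free when its snow-free fraction is at or
#' above the threshold ("50% or more" is inclusive). Standard scenarios use
#' thresholds 0.8, 0.5 and 0.3.
#'
#' @param frac snow-free-fraction grid in \[0, 1\].
#' @param t threshold in (0, 1\].
#' @return binary grid (1 = snow-free cell); `NA` propagated.
#' @export
threshold_mask <- function(frac, t) {
  if (t <= 0 || t > 1) stop("`t` must lie in (0, 1]")
  grid_like(frac, (frac$values >= t) + 0)
}

#' Label connected snow-free patches
#'
#' Connected-component labeling of a binary mask; 8-connectivity (diagonal
#' touch joins) by default because wind-scoured ridge crests often run
#' diagonally across grid axes.
#'
#' @param mask binary grid (`NA` treated as background).
#' @param connectivity 4 or 8.
#' @return a `snowsel_patches` object: `labels` (integer grid, 0 background,
#'   patches numbered 1..n), `table` (data.frame: `id`, `n_cells`, `area_m2`,
#'   `centroid_x`, `centroid_y`), `cell` size, `connectivity`.
#' @export
label_patches <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  v <- mask$values
  v[is.na(v)] <- 0
  nr <- nrow(v); nc <- ncol(v)
  fg <- which(v == 1)
  lab <- matrix(0L, nr, nc)
  if (length(fg)) {
    # adjacency edges between foreground cells via index shifts
    shifts <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
    r <- ((fg - 1L) %% nr) + 1L
    cc <- ((fg - 1L) %/% nr) + 1L
    inside <- matrix(FALSE, nr, nc); inside[fg] <- TRUE
    edges <- lapply(shifts, function(s) {
      r2 <- r + s[1]; c2 <- cc + s[2]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      ok[ok] <- inside[cbind(r2[ok], c2[ok])]
      cbind(fg[ok], (c2[ok] - 1L) * nr + r2[ok])
    })
    edges <- do.call(rbind, edges)
    # vertices are the foreground cells; map linear indices to 1..m
    vid <- integer(nr * nc); vid[fg] <- seq_along(fg)
    gph <- igraph::graph_from_edgelist(
      cbind(vid[edges[, 1]], vid[edges[, 2]]), directed = FALSE)
    gph <- igraph::add_vertices(gph, max(0L, length(fg) - igraph::vcount(gph)))
    comp <- igraph::components(gph)$membership
    # renumber components in first-encounter (column-major) order
    first <- match(unique(comp), comp)
    renum <- integer(max(comp)); renum[comp[sort(first)]] <- seq_along(first)
    lab[fg] <- renum[comp]
  }
  n <- if (length(fg)) max(lab) else 0L
  if (n > 0) {
    idx <- which(lab > 0)
    id <- lab[idx]
    cx <- mask$origin_x + (((idx - 1L) %/% nr) + 0.5) * mask$cell
    cy <- mask$origin_y - (((idx - 1L) %% nr) + 0.5) * mask$cell
    tab <- data.frame(
      id = seq_len(n),
      n_cells = as.integer(tabulate(id, n)),
      centroid_x = as.numeric(tapply(cx, id, mean)),
      centroid_y = as.numeric(tapply(cy, id, mean))
    )
    tab$area_m2 <- tab$n_cells * mask$cell^2
    tab <- tab[, c("id", "n_cells", "area_m2", "centroid_x", "centroid_y")]
  } else {
    tab <- data.frame(id = integer(0), n_cells = integer(0),
                      area_m2 = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0))
  }
  structure(list(labels = grid_like(mask, lab), table = tab,
                 cell = mask$cell, connectivity = connectivity),
            class = "snowsel_patches")
}

#' @export
print.snowsel_patches <- function(x, ...) {
  cat(sprintf("<snowsel_patches> %d patches, %d cells, %g m cells, %d-connectivity\n",
              nrow(x$table), sum(x$table$n_cells), x$cell, x$connectivity))
  invisible(x)
}

#' Remove patch cells inside exclusion polygons
#'
#' Cells whose centers fall inside any exclusion polygon (e.g. misclassified
#' forest margins, or land tongues unused by the animals) are removed and the
#' remaining mask relabeled. The excluded share of the original patch area is
#' reported.
#'
#' @param ps a `snowsel_patches`.
#' @param polygons list of two-column matrices (x, y vertex rings, closed or
#'   open).
#' @return a `snowsel_patches` with an extra `excluded_pct` field.
#' @export
apply_exclusions <- function(ps, polygons) {
  lab <- ps$labels
  if (!length(polygons)) {
    ps$excluded_pct <- 0
    return(ps)
  }
  nr <- nrow(lab$values)
  idx <- which(lab$values > 0)
  if (!length(idx)) {
    ps$excluded_pct <- 0
    return(ps)
  }
  cx <- lab$origin_x + (((idx - 1L) %/% nr) + 0.5) * lab$cell
  cy <- lab$origin_y - (((idx - 1L) %% nr) + 0.5) * lab$cell
  excl <- rep(FALSE, length(idx))
  for (p in polygons) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p)))
      stop("invalid exclusion polygon: need a finite n x 2 vertex matrix")
    excl <- excl | mgcv::in.out(rbind(p, p[1, ]), cbind(cx, cy))
  }
  keep <- matrix(0, nrow(lab$values), ncol(lab$values))
  keep[idx[!excl]] <- 1
  out <- label_patches(grid_like(lab, keep), connectivity = ps$connectivity)
  out$excluded_pct <- 100 * sum(excl) / length(idx)
  out
}

# Exact edge-to-edge Euclidean distance between two axis-aligned square cells
# given center offsets: each axis gap shrinks by one cell size, floored at 0.
edge_gap <- function(dx, dy, cell) {
  sqrt(pmax(abs(dx) - cell, 0)^2 + pmax(abs(dy) - cell, 0)^2)
}

# Boundary cells of each patch (cells with a 4-neighbor outside the patch).
boundary_cells <- function(lab) {
  v <- lab$values
  nr <- nrow(v); nc <- ncol(v)
  pad <- function(m) rbind(0L, cbind(0L, m, 0L), 0L)
  p <- pad(v)
  core <- p[2:(nr + 1), 2:(nc + 1)]
  is_b <- core > 0 & (p[1:nr, 2:(nc + 1)] != core |
                      p[3:(nr + 2), 2:(nc + 1)] != core |
                      p[2:(nr + 1), 1:nc] != core |
                      p[2:(nr + 1), 3:(nc + 2)] != core)
  which(is_b)
}

#' Patch size and spacing statistics
#'
#' Patch-size distribution and between-patch nearest-neighbor distances.
#' Distance is the minimum edge-to-edge Euclidean gap between cell squares of
#' distinct patches (0 for patches whose cells touch at an edge or corner);
#' `mode = "centroid"` measures centroid-to-centroid instead.
#'
#' @param ps a `snowsel_patches`.
#' @param mode "edge" (default) or "centroid".
#' @return list: `n_patches`, `area_median_m2`, `area_quantiles_m2`,
#'   `nn_dist_m` (per-patch nearest-neighbor distance, empty when < 2
#'   patches, with `distances_defined` flag), `nn_median_m`,
#'   `frac_within_100m`.
#' @export
patch_stats <- function(ps, mode = c("edge", "centroid")) {
  mode <- match.arg(mode)
  tab <- ps$table
  n <- nrow(tab)
  qs <- if (n) stats::quantile(tab$area_m2, c(0.25, 0.5, 0.75)) else
    stats::setNames(rep(NA_real_, 3), c("25%", "50%", "75%"))
  out <- list(n_patches = n,
              area_median_m2 = if (n) stats::median(tab$area_m2) else NA_real_,
              area_quantiles_m2 = qs,
              distances_defined = n >= 2)
  if (n < 2) {
    out$nn_dist_m <- numeric(0)
    out$nn_median_m <- NA_real_
    out$frac_within_100m <- NA_real_
    return(out)
  }
  if (mode == "centroid") {
    d <- as.matrix(stats::dist(tab[, c("centroid_x", "centroid_y")]))
    diag(d) <- Inf
    nn <- apply(d, 1, min)
  } else {
    lab <- ps$labels
    nr <- nrow(lab$values)
    bidx <- boundary_cells(lab)
    bid <- lab$values[bidx]
    bx <- lab$origin_x + (((bidx - 1L) %/% nr) + 0.5) * lab$cell
    by <- lab$origin_y - (((bidx - 1L) %% nr) + 0.5) * lab$cell
    cells <- split(data.frame(x = bx, y = by), bid)
    cen <- as.matrix(tab[, c("centroid_x", "centroid_y")])
    dcen <- as.matrix(stats::dist(cen))
    diag(dcen) <- Inf
    # patch radius bounds how far a patch's cells stray from its centroid
    radius <- vapply(seq_len(n), function(i) {
      b <- cells[[as.character(i)]]
      max(sqrt((b$x - cen[i, 1])^2 + (b$y - cen[i, 2])^2))
    }, 0)
    nn <- vapply(seq_len(n), function(i) {
      ord <- order(dcen[i, ])
      # exact: a patch whose centroid-distance lower bound exceeds the best
      # gap found so far cannot hold the minimum and is skipped
      best <- Inf
      for (j in ord) {
        if (j == i) next
        if (dcen[i, j] - radius[i] - radius[j] - sqrt(2) * lab$cell > best)
          next
        bi <- cells[[as.character(i)]]
        bj <- cells[[as.character(j)]]
        dx <- outer(bi$x, bj$x, `-`)
        dy <- outer(bi$y, bj$y, `-`)
        best <- min(best, min(edge_gap(dx, dy, lab$cell)))
      }
      best
    }, 0)
  }
  out$nn_dist_m <- as.numeric(nn)
  out$nn_median_m <- stats::median(nn)
  out$frac_within_100m <- mean(nn <= 100)
  out
}

#' Distance to the nearest snow-free cell
#'
#' Exact Euclidean distance transform (center-to-center, in meters); 0 on
#' qualifying cells. Optionally only patches at least `min_patch_area` m2
#' qualify (e.g. 1,800 m2, the median patch size, for distance to a
#' median-sized patch).
#'
#' @param mask binary snow-free grid.
#' @param min_patch_area minimum qualifying patch area (m2).
#' @param connectivity patch connectivity used for the area filter.
#' @return distance grid (m); all-`NA` when no cell qualifies.
#' @export
distance_to_snowfree <- function(mask, min_patch_area = 0, connectivity = 8) {
  v <- mask$values
  v[is.na(v)] <- 0
  if (min_patch_area > 0) {
    ps <- label_patches(grid_like(mask, v), connectivity = connectivity)
    small <- ps$table$id[ps$table$area_m2 < min_patch_area]
    v[ps$labels$values %in% small] <- 0
  }
  if (!any(v == 1))
    return(grid_like(mask, matrix(NA_real_, nrow(v), ncol(v))))
  d <- EBImage::distmap(1 - v, metric = "euclidean")
  grid_like(mask, as.matrix(d) * mask$cell)
}
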
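frac30 <- function(m) grid_create(as.matrix(m), 0, nrow(as.matrix(m)) * 30, 30)

test_that("threshold masks are inclusive at the cut ('50% or more')", {
  fr <- frac30(matrix(c(0.5, 0.499, 0.8, 0.79, 1, 0), 2, 3))
  m5 <- threshold_mask(fr, 0.5)
  expect_equal(m5$values[1, 1], 1)   # exactly 50% counts as snow-free
  expect_equal(m5$values[2, 1], 0)   # 49.9% does not
  m8 <- threshold_mask(fr, 0.8)
  expect_equal(sum(m8$values), 2)
  expect_equal(sum(threshold_mask(fr, 1)$values), 1)  # strictest keeps y = 1
  expect_error(threshold_mask(fr, 0), "0, 1")
})

test_that("patch labeling respects connectivity", {
  m <- matrix(0, 4, 4); m[2, 2] <- 1; m[3, 3] <- 1    # diagonal touch
  ps8 <- label_patches(frac30(m), connectivity = 8)
  ps4 <- label_patches(frac30(m), connectivity = 4)
  expect_equal(nrow(ps8$table), 1)
  expect_equal(nrow(ps4$table), 2)

  single <- label_patches(frac30(matrix(c(1, 0, 0, 0), 2, 2)))
  expect_equal(single$table$area_m2, 900)             # one 30 m cell
  two <- label_patches(frac30(matrix(c(1, 1, 0, 0), 2, 2)))
  expect_equal(two$table$area_m2, 1800)               # two 30 m cells

  empty <- label_patches(frac30(matrix(0, 3, 3)))
  expect_equal(nrow(empty$table), 0)
  expect_error(label_patches(frac30(matrix(0, 2, 2)), connectivity = 6))
})

test_that("4-connectivity labeling matches an independent image-processing oracle", {
  set.seed(99)
  for (i in 1:5) {
    m <- matrix(rbinom(400, 1, 0.35), 20, 20)
    ours <- label_patches(frac30(m), connectivity = 4)
    oracle <- EBImage::bwlabel(m)
    expect_equal(nrow(ours$table), max(oracle))
    # identical partitions: cells share our label iff they share the oracle's
    expect_equal(length(unique(paste(ours$labels$values, as.vector(oracle)))),
                 max(oracle) + 1L)
  }
})

test_that("patch areas sum to the labeled area and labels are contiguous", {
  set.seed(7)
  m <- matrix(rbinom(900, 1, 0.3), 30, 30)
  ps <- label_patches(frac30(m))
  expect_equal(sum(ps$table$n_cells), sum(m))
  expect_equal(sum(ps$table$area_m2), sum(m) * 900)
  expect_equal(sort(unique(as.vector(ps$labels$values[ps$labels$values > 0]))),
               seq_len(nrow(ps$table)))
  expect_equal(ps$table$area_m2, ps$table$n_cells * 900)
})

test_that("raising the threshold never increases total patch area", {
  cfg <- small_cfg(seed = 13)
  b <- generate_bundle(cfg)
  areas <- vapply(c(0.8, 0.5, 0.3), function(t) {
    ps <- label_patches(threshold_mask(b$snow_fraction_true, t))
    sum(ps$table$area_m2)
  }, 0)
  expect_true(areas[1] <= areas[2] && areas[2] <= areas[3])
})

test_that("exclusion polygons remove intersecting cells and report the share", {
  m <- matrix(0, 4, 4); m[2, 2:3] <- 1                 # one 2-cell patch
  ps <- label_patches(frac30(m))
  expect_equal(apply_exclusions(ps, list())$excluded_pct, 0)  # identity

  all_poly <- cbind(c(-10, 130, 130, -10), c(-10, -10, 130, 130))
  gone <- apply_exclusions(ps, list(all_poly))
  expect_equal(nrow(gone$table), 0)
  expect_equal(gone$excluded_pct, 100)

  # polygon covering the center of one of the two cells leaves a 1-cell patch
  half <- cbind(c(30, 60, 60, 30), c(0, 0, 120, 120))
  part <- apply_exclusions(ps, list(half))
  expect_equal(nrow(part$table), 1)
  expect_equal(part$table$area_m2, 900)
  expect_equal(part$excluded_pct, 50)
  expect_error(apply_exclusions(ps, list(cbind(0, 0))), "invalid")
})

test_that("between-patch distances are edge-to-edge gaps", {
  # two single cells in one row, two empty cells between: gap = 2 x 30 m
  m <- matrix(0, 3, 5); m[2, 1] <- 1; m[2, 4] <- 1
  st <- patch_stats(label_patches(frac30(m)))
  expect_equal(st$nn_dist_m, c(60, 60))
  expect_equal(st$nn_median_m, 60)
  expect_equal(st$frac_within_100m, 1)

  # diagonally adjacent cells are distinct under 4-connectivity but their
  # corners touch: edge gap 0
  d <- matrix(0, 3, 3); d[1, 1] <- 1; d[2, 2] <- 1
  st4 <- patch_stats(label_patches(frac30(d), connectivity = 4))
  expect_equal(st4$nn_dist_m, c(0, 0))

  # centroid mode measures center-to-center
  stc <- patch_stats(label_patches(frac30(m)), mode = "centroid")
  expect_equal(stc$nn_dist_m, c(90, 90))

  one <- patch_stats(label_patches(frac30(matrix(c(1, 0, 0, 0), 2, 2))))
  expect_false(one$distances_defined)
  expect_length(one$nn_dist_m, 0)
})

test_that("edge-gap distances agree with brute force on random mosaics", {
  set.seed(17)
  for (i in 1:3) {
    m <- matrix(rbinom(225, 1, 0.2), 15, 15)
    ps <- label_patches(frac30(m))
    if (nrow(ps$table) < 2) next
    st <- patch_stats(ps)
    # brute force over all cell pairs of distinct patches
    idx <- which(ps$labels$values > 0)
    lab <- ps$labels$values[idx]
    cx <- ((idx - 1) %/% 15 + 0.5) * 30
    cy <- ps$labels$origin_y - ((idx - 1) %% 15 + 0.5) * 30
    brute <- vapply(seq_len(nrow(ps$table)), function(p) {
      mine <- lab == p
      dx <- abs(outer(cx[mine], cx[!mine], `-`))
      dy <- abs(outer(cy[mine], cy[!mine], `-`))
      min(sqrt(pmax(dx - 30, 0)^2 + pmax(dy - 30, 0)^2))
    }, 0)
    expect_equal(st$nn_dist_m, brute)
  }
})

test_that("distance to snow-free is a Euclidean transform with a patch-size filter", {
  m <- matrix(0, 5, 5); m[3, 1] <- 1
  d <- distance_to_snowfree(frac30(m))
  expect_equal(d$values[3, 1], 0)        # on-patch cells are at distance 0
  expect_equal(d$values[3, 2], 30)       # one cell away, center-to-center
  expect_equal(d$values[3, 3], 60)
  expect_equal(d$values[1, 1], 60)

  # a single 900 m2 cell is below the 1,800 m2 median-patch filter
  d2 <- distance_to_snowfree(frac30(m), min_patch_area = 1800)
  expect_true(all(is.na(d2$values)))
  m2 <- m; m2[3, 2] <- 1                 # 2-cell patch passes the filter
  d3 <- distance_to_snowfree(frac30(m2), min_patch_area = 1800)
  expect_equal(d3$values[3, 1], 0)

  # non-negative everywhere and triangle inequality on sampled cell pairs
  set.seed(5)
  mm <- matrix(rbinom(400, 1, 0.1), 20, 20)
  dd <- distance_to_snowfree(frac30(mm))
  expect_true(all(dd$values >= 0))
  nr <- 20
  for (k in 1:50) {
    a <- sample(400, 1); b <- sample(400, 1)
    ax <- ((a - 1) %/% nr + 0.5) * 30; ay <- ((a - 1) %% nr + 0.5) * 30
    bx <- ((b - 1) %/% nr + 0.5) * 30; by <- ((b - 1) %% nr + 0.5) * 30
    dab <- sqrt((ax - bx)^2 + (ay - by)^2)
    expect_lte(dd$values[a], dd$values[b] + dab + 1e-9)
  }
})
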
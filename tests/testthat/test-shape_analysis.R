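test_that("contour extraction finds filled components with the documented conventions", {
  expect_length(extract_contours(matrix(FALSE, 10, 10)), 0L)

  sq <- matrix(FALSE, 20, 20); sq[3:12, 5:14] <- TRUE
  ct <- extract_contours(sq)
  expect_length(ct, 1L)
  expect_equal(ct[[1]]$area, 100)
  expect_equal(unname(ct[[1]]$centroid), c(8.5, 6.5))  # 0-based (x, y)
  expect_true(nrow(ct[[1]]$boundary) > 0)
  # boundary points lie inside the component (0-based coords)
  expect_true(all(sq[cbind(ct[[1]]$boundary[, 2] + 1L,
                           ct[[1]]$boundary[, 1] + 1L)]))

  two <- raster_disk(60, 15, 15, 8) | raster_disk(60, 45, 45, 8)
  expect_length(extract_contours(two), 2L)

  # diagonally touching pixels belong to one 8-connected object
  diag2 <- matrix(FALSE, 6, 6); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_length(extract_contours(diag2), 1L)
})

test_that("holes are filled before area and moments are computed", {
  ring <- raster_disk(41, 21, 21, 12) & !raster_disk(41, 21, 21, 6)
  ct <- extract_contours(ring)
  expect_length(ct, 1L)
  expect_equal(ct[[1]]$area, sum(raster_disk(41, 21, 21, 12)))
  expect_equal(hu_circularity(ct[[1]]), hu_oracle(raster_disk(41, 21, 21, 12)),
               tolerance = 1e-12)
})

test_that("component areas agree with a flood-fill oracle on random blobs", {
  set.seed(31)
  for (rep in 1:8) {
    mask <- matrix(runif(30 * 30) < 0.35, 30, 30)
    mask <- morphological_filter(mask, 1L)
    ct <- extract_contours(mask)
    oracle <- sort(component_sizes_oracle(fill_holes_for_test(mask)))
    expect_equal(sort(vapply(ct, function(x) x$area, numeric(1))), oracle)
  }
})

test_that("the area filter converts the radius criterion to pi r^2 exactly", {
  mk <- function(r) {
    ct <- extract_contours(raster_disk(2 * ceiling(r) + 9, ceiling(r) + 5,
                                       ceiling(r) + 5, r))
    ct[[1]]
  }
  big <- mk(12); small <- mk(5)
  kept <- area_filter(list(big, small), min_radius = 10)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$area, big$area)            # order preserved, r5 dropped
  expect_length(area_filter(list(big, small), min_radius = 0.5), 2L)
  expect_error(area_filter(list(big), min_radius = 0), "positive")
  # decision matches the arithmetic oracle on both sides of the cutoff
  expect_true(big$area >= pi * 100)
  expect_true(small$area < pi * 100)
})

test_that("disk circularity approaches the analytic circle constant", {
  disk <- raster_disk(101, 51, 51, 30)
  v <- hu_circularity(extract_contours(disk)[[1]])
  expect_lt(abs(v - (-log10(1 / (2 * pi)))), 0.01)
  expect_equal(v, hu_oracle(disk), tolerance = 1e-12)
})

test_that("circularity is invariant under translation, scale and rotation", {
  a <- hu_circularity(raster_disk(81, 25, 30, 15))
  b <- hu_circularity(raster_disk(81, 52, 41, 15))
  expect_equal(a, b, tolerance = 1e-14)             # translation: exact

  expect_lt(abs(hu_circularity(raster_disk(81, 41, 41, 15)) -
                hu_circularity(raster_disk(161, 81, 81, 30))), 0.005)

  rot_rect <- function(n, hw, hh, theta) {
    outer(seq_len(n) - n / 2, seq_len(n) - n / 2, function(y, x) {
      xr <- x * cos(theta) + y * sin(theta)
      yr <- -x * sin(theta) + y * cos(theta)
      abs(xr) <= hw & abs(yr) <= hh
    })
  }
  r0 <- hu_circularity(rot_rect(101, 20, 12, 0))
  r37 <- hu_circularity(rot_rect(101, 20, 12, 37 * pi / 180))
  expect_lt(abs(r0 - r37), 0.005)
})

test_that("elongated shapes score far below the circle constant", {
  rect <- matrix(TRUE, 10, 100)
  expect_lt(hu_circularity(rect), 0.5)
  expect_error(hu_circularity(matrix(FALSE, 5, 5)), "degenerate")
})

test_that("fused-disk circularity decreases as centres separate", {
  scores <- vapply(c(0, 4, 8, 12, 16, 20), function(d) {
    hu_circularity(raster_disk(80, 30, 40, 10) | raster_disk(80, 30 + d, 40, 10))
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_lte(scores[4], 0.76)                       # centres 12 px apart
})

test_that("circularity routing assigns one cell to each circular contour", {
  disk <- extract_contours(raster_disk(51, 26, 26, 12))[[1]]
  pair <- extract_contours(raster_disk(64, 22, 32, 10) |
                           raster_disk(64, 40, 32, 10))[[1]]  # d = 18
  cls <- classify_circularity(list(disk, pair), cutoff = 0.7)
  expect_length(cls$circular, 1L)
  expect_length(cls$non_circular, 1L)
  expect_equal(cls$circular[[1]]$cell_count, 1L)
  expect_true(is.na(cls$non_circular[[1]]$cell_count))
  expect_gte(cls$circular[[1]]$circularity, 0.7)
  expect_lt(cls$non_circular[[1]]$circularity, 0.7)

  everything <- classify_circularity(list(disk, pair), cutoff = 1e-6)
  expect_length(everything$non_circular, 0L)
  nothing <- classify_circularity(list(disk, pair), cutoff = 0.799)
  expect_length(nothing$circular, 0L)               # no raster shape beats a disk
})
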
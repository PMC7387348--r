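small_spec <- function(n_circles = c(5L, 25L), ...)
  synthetic_spec(n_circles = n_circles, width = 640L, height = 640L, ...)

test_that("fabrication is byte-identical given a seed and varies across seeds", {
  a <- fabricate_cfos_image(small_spec(), seed = 9)
  b <- fabricate_cfos_image(small_spec(), seed = 9)
  expect_identical(unclass(a$image)[, ], unclass(b$image)[, ])
  expect_identical(a$truth, b$truth)
  c <- fabricate_cfos_image(small_spec(), seed = 10)
  expect_false(identical(unclass(a$image)[, ], unclass(c$image)[, ]))
})

test_that("circle counts stay inside the configured range", {
  for (s in 1:5) {
    fab <- fabricate_cfos_image(synthetic_spec(), seed = 200 + s)
    n <- nrow(fab$truth$circles)
    expect_gte(n, 5L); expect_lte(n, 100L)
  }
})

test_that("ground truth equals an independent recount of the criteria", {
  cfg <- scc_config()
  for (s in 1:4) {
    fab <- fabricate_cfos_image(small_spec(), cfg, seed = 300 + s)
    circ <- fab$truth$circles
    recount <- 0L
    for (i in seq_len(nrow(circ)))                   # brute-force loop oracle
      if (circ$intensity[i] < cfg$threshold && circ$r[i] >= cfg$min_radius)
        recount <- recount + 1L
    expect_identical(fab$truth$gt_count, recount)
    expect_lte(fab$truth$gt_count, nrow(circ))
  }
})

test_that("single forced circles qualify exactly when dark enough and large enough", {
  one <- function(intensity_range, dark, r) {
    spec <- synthetic_spec(n_circles = c(1L, 1L), radius_range = c(r, r),
                           intensity_dark = intensity_range,
                           intensity_bright = intensity_range,
                           dark_frac = if (dark) 1 else 0,
                           width = 128L, height = 128L)
    fabricate_cfos_image(spec, scc_config(), seed = 5)$truth$gt_count
  }
  expect_equal(one(c(80, 80), dark = TRUE, r = 12), 1L)    # dark, big enough
  expect_equal(one(c(150, 150), dark = FALSE, r = 12), 0L) # too light
  expect_equal(one(c(80, 80), dark = TRUE, r = 8), 0L)     # too small
})

test_that("the background stays above threshold so blank regions are clean", {
  fab <- fabricate_cfos_image(small_spec(n_circles = c(5L, 5L)), seed = 12)
  img <- unclass(fab$image)
  circ <- fab$truth$circles
  far <- matrix(TRUE, nrow(img), ncol(img))
  for (i in seq_len(nrow(circ))) {
    ys <- pmax(1, floor(circ$y[i] - circ$r[i] - 3)):pmin(nrow(img), ceiling(circ$y[i] + circ$r[i] + 3))
    xs <- pmax(1, floor(circ$x[i] - circ$r[i] - 3)):pmin(ncol(img), ceiling(circ$x[i] + circ$r[i] + 3))
    far[ys, xs] <- FALSE
  }
  expect_gt(min(img[far]), 115)
})

test_that("overlap patches have the promised topology and labels", {
  # a single-disk patch is circular
  p1 <- make_overlap_patch(1, seed = 21)
  expect_equal(p1$label, 1L)
  expect_gte(hu_circularity(extract_contours(p1$patch)[[1]]), 0.78)

  # k fused disks always give exactly one external contour
  for (k in 2:4) for (s in 1:8) {
    p <- make_overlap_patch(k, seed = 1000 * k + s)
    expect_length(extract_contours(p$patch), 1L)
    expect_equal(p$label, k)
  }

  expect_false(identical(make_overlap_patch(2, seed = 1)$patch,
                         make_overlap_patch(2, seed = 2)$patch))
  expect_error(make_overlap_patch(5, seed = 1), "1..4")
})

test_that("every disk in a generated cluster keeps a visible lobe", {
  nn <- asNamespace("sccount")
  set.seed(55)
  for (k in 3:4) for (rep in 1:10) {
    r <- 20 * runif(k, 0.7, 1.3)
    g <- nn$cluster_geometry(r, c(0.6, 1.6), min_exposed = 0.5)
    expect_gte(nn$min_exposure(g[, 1], g[, 2], r), 0.5)
  }
})

test_that("an image too small for its circles fails loudly", {
  spec <- synthetic_spec(n_circles = c(60L, 60L), width = 96L, height = 96L)
  expect_error(fabricate_cfos_image(spec, seed = 1), "too small")
})

test_that("batches write images plus a parseable ground-truth table", {
  dir <- file.path(withr::local_tempdir(), "fab")
  out <- fabricate_batch(3L, small_spec(), scc_config(), seed = 31, dir = dir)
  expect_length(out, 3L)
  pngs <- list.files(dir, pattern = "\\.png$")
  expect_length(pngs, 3L)
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_setequal(unique(gt$image_id), c("fab_001", "fab_002", "fab_003"))
  per_img <- tapply(gt$qualifies, gt$image_id, sum)
  stated <- tapply(gt$gt_count, gt$image_id, unique)
  expect_equal(as.integer(per_img), as.integer(stated))
})
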
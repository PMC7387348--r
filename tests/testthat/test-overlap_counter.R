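test_that("patch normalization is translation-invariant and scale-normalizing", {
  at <- function(cx, cy, r, n = 96) make_patch(extract_contours(raster_disk(n, cx, cy, r))[[1]])
  p1 <- at(30, 30, 12)
  p2 <- at(60, 45, 12)
  expect_identical(unclass(p1)[, ], unclass(p2)[, ])  # exact translation removal

  p_big <- at(48, 48, 24)
  expect_gte(mean(p1 == p_big), 0.98)               # x2 scaling, resampling only

  # the disk fills the padded frame: foreground centred, margins clear
  expect_gt(sum(p1), 0.5 * 64^2 * pi / 4)
  expect_false(any(p1[1:2, ])); expect_false(any(p1[, 1:2]))
})

test_that("network gradients match numerical differentiation", {
  nn <- asNamespace("sccount")
  set.seed(42)
  specs <- list(nn$pool_spec(8L, 8L, 1L, 2L, "avg"),
                nn$conv_spec(4L, 4L, 1L, 3L, 2L),
                nn$pool_spec(2L, 2L, 2L, 2L, "max"),
                nn$dense_spec(2L, 3L, relu = TRUE),
                nn$dense_spec(3L, 4L, relu = FALSE))
  params <- nn$nn_init(specs)
  # nudge biases off zero so no ReLU sits exactly on its kink
  for (i in seq_along(params))
    if (!is.null(params[[i]]))
      params[[i]]$b <- rnorm(length(params[[i]]$b), 0, 0.3)
  X <- matrix(runif(5 * 64), 5, 64)
  lab <- c(1L, 2L, 3L, 4L, 2L)
  fw <- nn$nn_forward(X, params, specs, keep_cache = TRUE)
  ls <- nn$xent_loss(fw$logits, lab)
  gr <- nn$nn_backward(ls$dlogits, fw$caches, params, specs, 5L)
  eps <- 1e-5
  worst <- 0
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (what in c("W", "b")) for (j in seq_along(params[[i]][[what]])) {
      up <- params; up[[i]][[what]][j] <- up[[i]][[what]][j] + eps
      dn <- params; dn[[i]][[what]][j] <- dn[[i]][[what]][j] - eps
      num <- (nn$xent_loss(nn$nn_forward(X, up, specs)$logits, lab)$loss -
              nn$xent_loss(nn$nn_forward(X, dn, specs)$logits, lab)$loss) / (2 * eps)
      ana <- if (what == "W") gr[[i]]$dW[j] else gr[[i]]$db[j]
      worst <- max(worst, abs(num - ana))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("training is reproducible for a fixed seed", {
  set.seed(99)
  probes <- lapply(1:6, function(i) make_overlap_patch(((i - 1) %% 4) + 1,
                                                       seed = 5000 + i)$patch)
  m1 <- train_overlap_model(n_per_class = 25, seed = 3, epochs = 2)
  m2 <- train_overlap_model(n_per_class = 25, seed = 3, epochs = 2)
  expect_identical(predict(m1, probes), predict(m2, probes))
  expect_identical(m1$params, m2$params)
})

test_that("training rejects insufficient or single-class data", {
  ps <- lapply(1:60, function(i) make_overlap_patch(1, seed = i)$patch)
  expect_error(train_overlap_model(patches = ps, labels = rep(1L, 60)),
               "insufficient")
  expect_error(train_overlap_model(patches = ps[1:30],
                                   labels = rep(c(1L, 2L), 15)),
               "at least 20")
})

test_that("contour counting guards degenerate inputs and untrained models", {
  expect_error(count_in_contour(list(), matrix(TRUE, 64, 64)), "not a trained")
  m <- suite_model()
  tiny <- matrix(FALSE, 64, 64); tiny[30:31, 30:33] <- TRUE
  expect_warning(n <- count_in_contour(m, tiny), "degenerate")
  expect_equal(n, 1L)
})

test_that("the area fallback rounds area multiples of a packed cell", {
  fake <- function(a) list(area = a)
  expect_equal(count_in_contour_fallback(fake(pi * 100), 10, k = 1.5), 1L)
  expect_equal(count_in_contour_fallback(fake(3 * pi * 100 * 1.5), 10, k = 1.5), 3L)
  expect_equal(count_in_contour_fallback(fake(1), 10), 1L)
  expect_error(count_in_contour_fallback(fake(0), 10), "positive")
})

test_that("model files round-trip and refuse version mismatches", {
  m <- suite_model()
  f <- withr::local_tempfile(fileext = ".rds")
  write_overlap_model(m, f)
  back <- read_overlap_model(f)
  probe <- make_overlap_patch(2, seed = 404)$patch
  expect_identical(predict(back, probe), predict(m, probe))
  bad <- m; bad$version <- "other"
  saveRDS(bad, f)
  expect_error(read_overlap_model(f), "compatible")
})

test_that("the suite classifier counts fresh overlap patches accurately", {
  m <- suite_model()
  acc <- m$holdout_accuracy$per_class
  expect_gte(mean(acc[c("1", "2")]), 0.90)          # module bar, classes {1,2}
  expect_gte(mean(acc[c("3", "4")]), 0.80)          # module bar, classes {3,4}

  # prediction is invariant to where the object sat in the source image
  big <- raster_disk(200, 50, 60, 11) | raster_disk(200, 66, 60, 11)
  shifted <- raster_disk(200, 130, 140, 11) | raster_disk(200, 146, 140, 11)
  c1 <- predict(m, make_patch(extract_contours(big)[[1]]))
  c2 <- predict(m, make_patch(extract_contours(shifted)[[1]]))
  expect_identical(c1, c2)
  expect_equal(c1, 2L)
})
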
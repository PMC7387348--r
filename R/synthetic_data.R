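#' Specification of a fabricated cFos-like image
#'
#' Describes how synthetic brightfield images are generated: a random
#' number of filled circles of varying intensity and size on a gray,
#' lightly noisy background resembling tissue background staining. Circle
#' intensities are drawn from two sub-ranges, one below the detection
#' threshold (dark, qualifying) and one above it (too light), so the ground
#' truth is non-trivial; radii bracket the default minimum radius so the
#' size filter is exercised. A small fraction of circles is placed as fused
#' clusters whose true multiplicities are recorded, keeping the ground
#' truth exact end to end.
#'
#' @param n_circles integer range (lo, hi) of circles per image.
#' @param radius_range radii are drawn uniformly from this range (pixels).
#' @param intensity_dark,intensity_bright intensity sub-ranges (0--255) for
#'   qualifying (dark) and non-qualifying (light) circles.
#' @param dark_frac probability a circle is drawn from the dark range.
#' @param background_level,background_noise_sd gray background mean and
#'   Gaussian noise standard deviation (intensity units; clipped to 0--255).
#' @param width,height image size in pixels.
#' @param cluster_probs probabilities that a placement is a single circle,
#'   a fused pair, or a fused triple.
#' @param overlap_dist fused centre distances are
#'   `u * (r_i + r_j) / 2` with `u` uniform in this range; `u < 2`
#'   guarantees overlap.
#' @param aa if `TRUE`, circle edges are anti-aliased (coverage-weighted
#'   blend); the default draws hard-edged circles as a standard circle
#'   rasterizer does.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_circles = c(5L, 100L), radius_range = c(8, 15),
                           intensity_dark = c(60, 110),
                           intensity_bright = c(125, 175), dark_frac = 0.5,
                           background_level = 180, background_noise_sd = 6,
                           width = 1024L, height = 1024L,
                           cluster_probs = c(single = 0.95, pair = 0.04, triple = 0.01),
                           overlap_dist = c(0.6, 1.6), aa = FALSE) {
  if (length(n_circles) != 2L || n_circles[1] < 1L || n_circles[1] > n_circles[2])
    stop("'n_circles' must be an increasing positive range")
  if (radius_range[1] <= 0 || radius_range[1] > radius_range[2])
    stop("'radius_range' must be an increasing positive range")
  if (background_level < 0 || background_level > 255)
    stop("'background_level' must lie in [0, 255]")
  if (abs(sum(cluster_probs) - 1) > 1e-8) stop("'cluster_probs' must sum to 1")
  if (overlap_dist[1] <= 0 || overlap_dist[2] >= 2)
    stop("'overlap_dist' must lie inside (0, 2) so fused circles overlap")
  structure(list(n_circles = as.integer(n_circles), radius_range = radius_range,
                 intensity_dark = intensity_dark,
                 intensity_bright = intensity_bright, dark_frac = dark_frac,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 width = as.integer(width), height = as.integer(height),
                 cluster_probs = cluster_probs, overlap_dist = overlap_dist,
                 aa = aa),
            class = "synthetic_spec")
}

resample1 <- function(v) v[sample.int(length(v), 1L)]

# Offsets for a fused cluster of k disks. Each disk after the first is
# attached to a previously placed one at centre distance u * (r_a + r_j)/2,
# u ~ U(overlap_dist), which guarantees pairwise overlap (u < 2) and hence a
# single connected component. Placements where any disk would be mostly
# swallowed by the union of the others are rejected and resampled, so every
# disk keeps at least `min_exposed` of its area visible and the cluster's
# cell count is identifiable from its silhouette.
cluster_geometry <- function(radii, overlap_dist, min_exposed = 0.35,
                             tries = 60L, restarts = 25L) {
  k <- length(radii)
  if (k == 1L) return(cbind(ox = 0, oy = 0))
  best_geom <- NULL; best_final <- -Inf
  for (rs in seq_len(restarts)) {
    ox <- numeric(k); oy <- numeric(k)
    for (j in 2:k) {
      best <- NULL; best_score <- -Inf
      for (t in seq_len(tries)) {
        a <- resample1(seq_len(j - 1L))
        u <- stats::runif(1, overlap_dist[1], overlap_dist[2])
        d <- u * (radii[a] + radii[j]) / 2
        ang <- stats::runif(1, 0, 2 * pi)
        ox[j] <- ox[a] + d * cos(ang); oy[j] <- oy[a] + d * sin(ang)
        score <- min_exposure(ox[1:j], oy[1:j], radii[1:j])
        if (score > best_score) { best_score <- score; best <- c(ox[j], oy[j]) }
        if (score >= min_exposed) break
      }
      ox[j] <- best[1]; oy[j] <- best[2]
    }
    final <- min_exposure(ox, oy, radii)
    if (final > best_final) { best_final <- final; best_geom <- cbind(ox, oy) }
    if (final >= min_exposed) break
  }
  best_geom
}

# Smallest visible-area fraction over the disks, on a unit-pixel raster.
min_exposure <- function(ox, oy, r) {
  x0 <- floor(min(ox - r)); y0 <- floor(min(oy - r))
  w <- ceiling(max(ox + r)) - x0 + 1L; h <- ceiling(max(oy + r)) - y0 + 1L
  xs <- seq_len(w) - 1 + x0; ys <- seq_len(h) - 1 + y0
  masks <- lapply(seq_along(r), function(i)
    outer((ys - oy[i])^2, (xs - ox[i])^2, `+`) <= r[i]^2)
  min(vapply(seq_along(masks), function(i) {
    others <- Reduce(`|`, masks[-i], matrix(FALSE, h, w))
    sum(masks[[i]] & !others) / max(1L, sum(masks[[i]]))
  }, numeric(1)))
}

#' Generate one fabricated cFos-like image with exact ground truth
#'
#' Draws `n ~ Uniform{n_circles}` filled circles at random positions over
#' the noisy gray background (darker circle wins where circles overlap).
#' Ground truth records every circle (centre, radius, intensity, cluster
#' id) and `gt_count`, the number of circles meeting the detection criteria
#' of `config`: intensity on the foreground side of the threshold and
#' radius at least `min_radius`. Isolated qualifying circles are circular
#' by construction; fused clusters contribute their recorded
#' multiplicities.
#'
#' @param spec a [synthetic_spec()].
#' @param config the [scc_config()] defining the qualification criteria.
#' @param seed integer seed; output is byte-identical for a given seed.
#' @return `list(image = gray_image, truth = list(circles = data.frame,
#'   gt_count = integer))`.
#' @export
fabricate_cfos_image <- function(spec = synthetic_spec(), config = scc_config(),
                                 seed = 1L) {
  with_local_seed(seed, {
    n <- resample1(seq.int(spec$n_circles[1], spec$n_circles[2]))
    circles <- plan_circles(n, spec)
    img <- render_circles(circles, spec)
    dark <- if (config$polarity == "dark_on_light")
      circles$intensity < config$threshold else circles$intensity > config$threshold
    circles$qualifies <- dark & circles$r >= config$min_radius
    list(image = gray_image(img),
         truth = list(circles = circles, gt_count = sum(circles$qualifies)))
  })
}

# Choose cluster sizes, geometry and placements; rejection-sample anchor
# positions so distinct clusters never touch (>= 3 px gap).
plan_circles <- function(n, spec) {
  sizes <- integer(0)
  while (sum(sizes) < n) {
    s <- resample1(rep.int(1:3, round(1000 * spec$cluster_probs)))
    sizes <- c(sizes, min(s, n - sum(sizes)))
  }
  out <- vector("list", length(sizes))
  placed_x <- numeric(0); placed_y <- numeric(0); placed_ext <- numeric(0)
  for (ci in seq_along(sizes)) {
    s <- sizes[ci]
    r <- stats::runif(s, spec$radius_range[1], spec$radius_range[2])
    geom <- cluster_geometry(r, spec$overlap_dist,
                             min_exposed = if (s >= 3L) 0.5 else 0.35)
    ox <- geom[, 1]; oy <- geom[, 2]
    ext <- max(sqrt(ox^2 + oy^2) + r)
    lo_x <- ext + 2; hi_x <- spec$width - 1 - ext - 2
    lo_y <- ext + 2; hi_y <- spec$height - 1 - ext - 2
    if (lo_x >= hi_x || lo_y >= hi_y)
      stop("image too small for the requested circles")
    ok <- FALSE
    for (try in seq_len(4000L)) {
      cx <- stats::runif(1, lo_x, hi_x); cy <- stats::runif(1, lo_y, hi_y)
      if (length(placed_x) == 0L ||
          all(sqrt((placed_x - cx)^2 + (placed_y - cy)^2) >=
              placed_ext + ext + 3)) { ok <- TRUE; break }
    }
    if (!ok) stop("image too small for the requested circles")
    placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
    placed_ext <- c(placed_ext, ext)
    dark <- stats::runif(s) < spec$dark_frac
    intensity <- ifelse(dark,
                        stats::runif(s, spec$intensity_dark[1], spec$intensity_dark[2]),
                        stats::runif(s, spec$intensity_bright[1], spec$intensity_bright[2]))
    out[[ci]] <- data.frame(x = cx + ox, y = cy + oy, r = r,
                            intensity = round(intensity), cluster = ci,
                            cluster_size = s)
  }
  df <- do.call(rbind, out)
  df$circle <- seq_len(nrow(df))
  df[, c("circle", "x", "y", "r", "intensity", "cluster", "cluster_size")]
}

render_circles <- function(circles, spec) {
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background_level +
                  stats::rnorm(h * w, 0, spec$background_noise_sd), h, w)
  img <- pmin(pmax(round(img), 0), 255)
  for (i in seq_len(nrow(circles))) {
    cx <- circles$x[i]; cy <- circles$y[i]; r <- circles$r[i]
    I <- circles$intensity[i]
    ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r + 2))  # 1-based rows
    xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r + 2))
    d <- sqrt(outer((ys - 1 - cy)^2, (xs - 1 - cx)^2, `+`))
    sub <- img[ys, xs, drop = FALSE]
    if (spec$aa) {
      cov <- pmin(pmax(r + 0.5 - d, 0), 1)
      sub <- pmin(sub, round(cov * I + (1 - cov) * sub))
    } else {
      sub[d <= r] <- pmin(sub[d <= r], I)
    }
    img[ys, xs] <- sub
  }
  img
}

#' Generate a batch of fabricated images
#'
#' @param n_images number of images.
#' @param spec a [synthetic_spec()].
#' @param config the [scc_config()] defining ground-truth criteria.
#' @param seed master seed; per-image seeds are derived from it.
#' @param dir optional output directory: writes `fab_###.png` plus a
#'   `ground_truth.csv` with one row per circle (image_id, circle fields,
#'   qualifies, gt_count).
#' @return List of `list(image_id, image, truth)`.
#' @export
fabricate_batch <- function(n_images = 15L, spec = synthetic_spec(),
                            config = scc_config(), seed = 1L, dir = NULL) {
  seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n_images))
  out <- lapply(seq_len(n_images), function(i) {
    fab <- fabricate_cfos_image(spec, config, seed = seeds[i])
    c(list(image_id = sprintf("fab_%03d", i)), fab)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gt <- do.call(rbind, lapply(out, function(o) {
      png::writePNG(unclass(o$image) / 255, file.path(dir, paste0(o$image_id, ".png")))
      cbind(data.frame(image_id = o$image_id, stringsAsFactors = FALSE),
            o$truth$circles, gt_count = o$truth$gt_count)
    }))
    utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  out
}

#' Generate one labelled overlapping-disk training patch
#'
#' Renders `k` fused disks (radii jittered +/-30% around a base radius,
#' centre distances `u * (r_i + r_j) / 2`, `u` uniform in `overlap_dist`,
#' each new disk overlapping an existing one so the cluster is a single
#' connected component), binarizes them and normalizes the result exactly
#' like [make_patch()].
#'
#' @param k number of cells in the patch (1--4).
#' @param seed integer seed.
#' @param size patch side (default 64).
#' @param base_radius_range base radius range before jitter.
#' @param overlap_dist centre-distance factor range.
#' @return `list(patch = logical size x size matrix, label = k)`.
#' @export
make_overlap_patch <- function(k, seed = 1L, size = 64L,
                               base_radius_range = c(18, 24),
                               overlap_dist = c(0.6, 1.6)) {
  if (!(k %in% 1:4)) stop("'k' must be in 1..4")
  with_local_seed(seed, {
    r0 <- stats::runif(1, base_radius_range[1], base_radius_range[2])
    r <- r0 * stats::runif(k, 0.7, 1.3)
    geom <- cluster_geometry(r, overlap_dist,
                             min_exposed = if (k >= 3L) 0.5 else 0.35)
    ox <- geom[, 1]; oy <- geom[, 2]
    pad <- 3
    x0 <- min(ox - r) - pad; y0 <- min(oy - r) - pad
    wpx <- ceiling(max(ox + r) - x0 + pad) + 1L
    hpx <- ceiling(max(oy + r) - y0 + pad) + 1L
    mask <- matrix(FALSE, hpx, wpx)
    for (j in seq_len(k)) {
      d <- sqrt(outer((seq_len(hpx) - 1 + y0 - oy[j])^2,
                      (seq_len(wpx) - 1 + x0 - ox[j])^2, `+`))
      mask <- mask | (d <= r[j])
    }
    ct <- extract_contours(mask)
    ct <- ct[[which.max(vapply(ct, function(x) x$area, numeric(1)))]]
    list(patch = make_patch(ct, size = size), label = as.integer(k))
  })
}
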
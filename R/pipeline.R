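#' Count cells in one grayscale image
#'
#' Runs the full four-step pipeline: global threshold, adaptive
#' morphological opening (iterations from the threshold/MPI ratio via the
#' configured schedule), contour extraction with hole filling, area filter,
#' Hu-moment circularity split, and overlap resolution. Circular contours
#' count one cell each; non-circular contours are normalized to patches and
#' counted by the overlap classifier (or, without a model, by the
#' deterministic area fallback, with a warning).
#'
#' @param img a [gray_image()] (or 0--255 numeric matrix).
#' @param config an [scc_config()].
#' @param model optional [train_overlap_model()] result.
#' @param image_id identifier used in result tables; defaults to the image
#'   source filename.
#' @param fallback_k packing constant of [count_in_contour_fallback()].
#' @return A list of class `count_result`: `image_id`, `total_count`,
#'   `circular_count`, `overlap_contour_count` (number of contours routed
#'   to the overlap counter), `per_contour` data frame, `boundaries` (for
#'   overlays), `mpi`, `iterations`. Always satisfies
#'   `total_count = circular_count + sum of non-circular counts`.
#' @export
count_cells <- function(img, config = scc_config(), model = NULL,
                        image_id = NULL, fallback_k = 1.5) {
  if (is.null(image_id)) {
    sp <- attr(img, "source_path")
    image_id <- if (!is.null(sp)) basename(sp) else "image"
  }
  mpi <- mean_pixel_intensity(img)
  if (mpi <= 0 || mpi >= 255) {
    warning("degenerate image '", image_id, "' (mean pixel intensity ", mpi,
            "); returning zero count")
    return(empty_count_result(image_id, mpi))
  }
  mask <- binarize(img, config$threshold, config$polarity)
  iters <- iteration_count(config$threshold, mpi, config$schedule)
  filt <- morphological_filter(mask, iters)
  kept <- area_filter(extract_contours(filt), config$min_radius)
  cls <- classify_circularity(kept, config$circularity_cutoff)

  non_circ <- cls$non_circular
  if (length(non_circ) > 0L) {
    if (is.null(model)) {
      warning("no overlap model supplied; using area-based fallback for ",
              length(non_circ), " non-circular contour(s)")
      counts <- vapply(non_circ, count_in_contour_fallback,
                       integer(1), min_radius = config$min_radius, k = fallback_k)
    } else {
      counts <- vapply(non_circ, function(ct)
        count_in_contour(model, make_patch(ct)), integer(1))
    }
    for (i in seq_along(non_circ)) non_circ[[i]]$cell_count <- counts[i]
  } else counts <- integer(0)

  circular_count <- length(cls$circular)
  total <- circular_count + sum(counts)
  stopifnot(total == circular_count + sum(counts), total >= circular_count)
  all_ct <- c(cls$circular, non_circ)
  all_ct <- all_ct[order(vapply(all_ct, function(ct) ct$id, integer(1)))]
  structure(list(image_id = image_id,
                 total_count = as.integer(total),
                 circular_count = as.integer(circular_count),
                 overlap_contour_count = length(non_circ),
                 per_contour = contour_df(all_ct),
                 boundaries = lapply(all_ct, function(ct) ct$boundary),
                 mpi = mpi, iterations = iters),
            class = "count_result")
}

empty_count_result <- function(image_id, mpi) {
  structure(list(image_id = image_id, total_count = 0L, circular_count = 0L,
                 overlap_contour_count = 0L, per_contour = contour_df(list()),
                 boundaries = list(), mpi = mpi, iterations = NA_integer_),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %s: %d cells (%d circular + %d from %d overlap contours); MPI %.1f, %s opening iteration(s)\n",
              x$image_id, x$total_count, x$circular_count,
              x$total_count - x$circular_count, x$overlap_contour_count,
              x$mpi, format(x$iterations)))
  invisible(x)
}

image_file_pattern <- "\\.(tiff?|png|jpe?g)$"

#' Count cells in every image of a folder
#'
#' Images are processed in sorted filename order, so runs are
#' deterministic. A file that fails to load or count is skipped with a
#' warning and the batch continues.
#'
#' @param folder directory containing TIFF/PNG/JPEG images.
#' @param config an [scc_config()].
#' @param model optional overlap model.
#' @param out optional summary CSV path (see [write_results()]).
#' @param per_contour_out optional per-contour CSV path.
#' @return List of `count_result`s.
#' @export
run_batch <- function(folder, config = scc_config(), model = NULL,
                      out = NULL, per_contour_out = NULL) {
  files <- sort(list.files(folder, pattern = image_file_pattern,
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no readable images found in: ", folder)
  results <- list()
  for (f in files) {
    res <- tryCatch(count_cells(load_grayscale(f), config, model),
                    error = function(e) {
                      warning("skipping '", basename(f), "': ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  if (!is.null(out)) write_results(results, out, per_contour_out)
  results
}

resize_gray <- function(img, new_w, new_h) {
  res <- EBImage::resize(EBImage::Image(t(unclass(img)) / 255),
                         w = new_w, h = new_h, filter = "bilinear")
  gray_image(pmin(pmax(t(EBImage::imageData(res)) * 255, 0), 255),
             source_path = attr(img, "source_path"))
}

#' Count across image sizes
#'
#' Each image is rescaled to `new size = original size / factor` (so a
#' factor of 0.5 enlarges) and counted with `min_radius` scaled by
#' `1/factor` to keep the size criterion commensurate. Wall-clock time per
#' image is reported as informational output only.
#'
#' @param folder image directory.
#' @param config an [scc_config()].
#' @param factors resize factors (> 0).
#' @param model optional overlap model.
#' @return Data frame with columns `factor`, `image_id`, `width`, `height`,
#'   `total_count`, `elapsed` (seconds). Images whose resized dimension
#'   would fall below 8 px are skipped with a warning.
#' @export
resize_sweep <- function(folder, config = scc_config(),
                         factors = c(0.5, 1, 2, 4, 6, 8, 10), model = NULL) {
  if (any(factors <= 0)) stop("resize factors must be positive")
  files <- sort(list.files(folder, pattern = image_file_pattern,
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no readable images found in: ", folder)
  rows <- list()
  for (f in files) {
    img <- load_grayscale(f)
    for (fac in factors) {
      new_w <- round(ncol(img) / fac); new_h <- round(nrow(img) / fac)
      if (min(new_w, new_h) < 8L) {
        warning("factor ", fac, " on '", basename(f),
                "' gives an image below 8 px; skipped")
        next
      }
      scaled <- if (fac == 1) img else resize_gray(img, new_w, new_h)
      cfg <- config
      cfg$min_radius <- config$min_radius / fac
      el <- system.time(res <- count_cells(scaled, cfg, model,
                                           image_id = basename(f)))[["elapsed"]]
      rows[[length(rows) + 1L]] <-
        data.frame(factor = fac, image_id = basename(f),
                   width = new_w, height = new_h,
                   total_count = res$total_count, elapsed = el)
    }
  }
  do.call(rbind, rows)
}

#' Count accuracy across threshold factors
#'
#' For each factor, every image is counted with an image-specific threshold
#' `factor * mean_pixel_intensity(image)` and the mean absolute error
#' against the aligned reference counts is reported.
#'
#' @param folder image directory (processed in sorted filename order).
#' @param config an [scc_config()] (its absolute threshold is ignored here).
#' @param factors threshold factors (fractions of the image MPI).
#' @param reference reference counts aligned to the sorted images.
#' @param model optional overlap model.
#' @return Data frame with columns `factor`, `mean_abs_error`.
#' @export
threshold_sweep <- function(folder, config = scc_config(),
                            factors = c(0.7, 0.75, 0.8, 0.85),
                            reference, model = NULL) {
  files <- sort(list.files(folder, pattern = image_file_pattern,
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no readable images found in: ", folder)
  if (length(reference) != length(files))
    stop("alignment error: 'reference' must have one count per image")
  imgs <- lapply(files, load_grayscale)
  rows <- lapply(factors, function(fac) {
    counts <- vapply(imgs, function(img) {
      cfg <- config
      cfg$threshold <- fac * mean_pixel_intensity(img)
      count_cells(img, cfg, model)$total_count
    }, integer(1))
    data.frame(factor = fac,
               mean_abs_error = abs_error(reference, counts)$mean_abs_error)
  })
  do.call(rbind, rows)
}
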
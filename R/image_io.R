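#' Construct an 8-bit grayscale image
#'
#' A `gray_image` is an integer matrix with values in 0--255, indexed
#' `[y, x]` (row-major, origin top-left). All pipeline coordinates are
#' 0-based: `x` is the column index minus 1, `y` the row index minus 1.
#'
#' @param pixels numeric or integer matrix; values must lie in 0--255.
#' @param source_path optional path the image was read from.
#' @return An integer matrix of class `gray_image`.
#' @export
gray_image <- function(pixels, source_path = NULL) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1")
  if (anyNA(pixels)) stop("image contains NA pixels")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  img <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  class(img) <- c("gray_image", class(img))
  attr(img, "source_path") <- source_path
  img
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d (h x w), intensities %d..%d, mean %.1f\n",
              nrow(x), ncol(x), min(x), max(x), mean(x)))
  sp <- attr(x, "source_path")
  if (!is.null(sp)) cat("  source:", sp, "\n")
  invisible(x)
}

# Luminance weights for RGB -> gray; rounded to nearest integer intensity.
.lum_weights <- c(0.299, 0.587, 0.114)

#' Load an image file as 8-bit grayscale
#'
#' Reads TIFF, PNG or JPEG. Multi-channel images are converted with the
#' standard luminance weighting (0.299 R + 0.587 G + 0.114 B), rounded to the
#' nearest integer. Higher bit depths are rescaled linearly onto 0--255
#' (a 16-bit sample is divided by 257), so absolute intensity thresholds
#' keep their meaning.
#'
#' @param path path to a readable TIFF/PNG/JPEG file.
#' @return A [gray_image()].
#' @export
load_grayscale <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read image file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  dat <- EBImage::imageData(img)  # [x, y] or [x, y, channel], values in [0, 1]
  if (length(dat) == 0L) stop("zero-sized image: ", path)
  if (length(dim(dat)) == 3L) {
    nc <- dim(dat)[3]
    w <- if (nc >= 3L) c(.lum_weights, rep(0, nc - 3L)) else rep(1 / nc, nc)
    dat <- apply_channel_weights(dat, w)
  }
  gray_image(t(round(dat * 255)), source_path = path)
}

apply_channel_weights <- function(arr, w) {
  out <- arr[, , 1] * w[1]
  for (k in seq_along(w)[-1]) if (w[k] != 0) out <- out + arr[, , k] * w[k]
  out
}

#' Mean pixel intensity of a grayscale image
#'
#' The arithmetic mean of all pixel values; the denominator of the
#' threshold/MPI ratio that drives the adaptive morphological filter.
#'
#' @param img a [gray_image()] or plain numeric matrix with values 0--255.
#' @return A real number in `[0, 255]`.
#' @export
mean_pixel_intensity <- function(img) {
  if (!is.matrix(img)) stop("'img' must be a matrix")
  mean(img)
}

#' Write per-image count results to CSV
#'
#' One row per image with columns `image_id`, `total_count`,
#' `circular_count`, `overlap_contour_count`. Optionally also writes the
#' per-contour table (`image_id`, `contour_id`, `centroid_x`, `centroid_y`,
#' `area`, `circularity`, `is_circular`, `cell_count`).
#'
#' @param results list of count results from [count_cells()].
#' @param out path of the summary CSV (header always written).
#' @param per_contour_out optional path for the per-contour CSV.
#' @return Invisibly, the summary data frame.
#' @export
write_results <- function(results, out, per_contour_out = NULL) {
  summary <- results_table(results)
  ok <- tryCatch({
    suppressWarnings(utils::write.csv(summary, out, row.names = FALSE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write results to: ", out)
  if (!is.null(per_contour_out)) {
    pc <- do.call(rbind, c(lapply(results, per_contour_table),
                           list(per_contour_table(NULL))))
    utils::write.csv(pc, per_contour_out, row.names = FALSE)
  }
  invisible(summary)
}

results_table <- function(results) {
  data.frame(
    image_id = vapply(results, function(r) r$image_id, character(1)),
    total_count = vapply(results, function(r) r$total_count, integer(1)),
    circular_count = vapply(results, function(r) r$circular_count, integer(1)),
    overlap_contour_count = vapply(results, function(r) r$overlap_contour_count, integer(1)),
    stringsAsFactors = FALSE
  )
}

per_contour_table <- function(result) {
  if (is.null(result) || nrow(result$per_contour) == 0L) {
    return(data.frame(image_id = character(0), contour_id = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      area = numeric(0), circularity = numeric(0),
                      is_circular = logical(0), cell_count = integer(0)))
  }
  cbind(data.frame(image_id = result$image_id, stringsAsFactors = FALSE),
        result$per_contour)
}

#' Write a PNG overlay with detected contour boundaries drawn in red
#'
#' @param img the counted [gray_image()].
#' @param result the matching [count_cells()] result.
#' @param out output PNG path.
#' @return Invisibly, `out`.
#' @export
write_overlay <- function(img, result, out) {
  g <- unclass(img) / 255
  rgb <- array(rep(g, 3L), dim = c(nrow(img), ncol(img), 3L))
  for (b in result$boundaries) {
    ii <- cbind(b[, 2] + 1L, b[, 1] + 1L)  # (y, x) 0-based -> row/col
    rgb[cbind(ii, 1L)] <- 1; rgb[cbind(ii, 2L)] <- 0; rgb[cbind(ii, 3L)] <- 0
  }
  png::writePNG(rgb, out)
  invisible(out)
}
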
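#' Default schedule of morphological iterations vs threshold/MPI ratio
#'
#' Noise-like speckle grows steeply as the threshold approaches the image
#' mean, so the opening is applied more aggressively at high ratios. The
#' schedule maps the ratio r = threshold / mean pixel intensity onto an
#' iteration count through ordered breakpoints; iterations must be
#' non-decreasing in the ratio.
#'
#' Default: r < 0.70 -> 1; 0.70 <= r < 0.80 -> 2; 0.80 <= r < 0.90 -> 3;
#' r >= 0.90 -> 4.
#'
#' @param upper upper bounds of the ratio bins (last is `Inf`).
#' @param iterations positive iteration count per bin, non-decreasing.
#' @return A data frame of class `iteration_schedule`.
#' @export
iteration_schedule <- function(upper = c(0.70, 0.80, 0.90, Inf),
                               iterations = c(1L, 2L, 3L, 4L)) {
  if (length(upper) != length(iterations) || length(upper) < 1L)
    stop("'upper' and 'iterations' must be equal-length, non-empty")
  if (is.unsorted(upper, strictly = TRUE)) stop("'upper' must be strictly increasing")
  if (any(iterations < 1L)) stop("iterations must be positive")
  if (is.unsorted(iterations)) stop("iterations must be non-decreasing in the ratio")
  s <- data.frame(upper = upper, iterations = as.integer(iterations))
  class(s) <- c("iteration_schedule", class(s))
  s
}

#' Pipeline configuration
#'
#' Bundles the user parameters of the counting pipeline. Defaults are the
#' standard settings for darkly stained cells: threshold 115, minimum cell
#' radius 10 px, circularity cutoff 0.7.
#'
#' @param threshold global intensity threshold, 0--255.
#' @param min_radius minimum cell radius in pixels; objects whose filled
#'   area is below `pi * min_radius^2` are discarded.
#' @param circularity_cutoff log-adjusted first-Hu-moment cutoff separating
#'   circular from non-circular contours. Must lie strictly between 0 and
#'   the perfect-disk value `-log10(1/(2*pi)) = 0.798`.
#' @param polarity `"dark_on_light"` (stained cells darker than background)
#'   or `"light_on_dark"` (e.g. fluorescence; the comparison is inverted).
#' @param schedule an [iteration_schedule()].
#' @return A list of class `scc_config`.
#' @export
scc_config <- function(threshold = 115, min_radius = 10,
                       circularity_cutoff = 0.7,
                       polarity = c("dark_on_light", "light_on_dark"),
                       schedule = iteration_schedule()) {
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255) stop("'threshold' must lie in [0, 255]")
  if (min_radius <= 0) stop("'min_radius' must be positive")
  disk_value <- -log10(1 / (2 * pi))
  if (circularity_cutoff <= 0 || circularity_cutoff >= disk_value)
    stop(sprintf("'circularity_cutoff' must lie in (0, %.3f)", disk_value))
  if (!inherits(schedule, "iteration_schedule")) schedule <- do.call(iteration_schedule, schedule)
  structure(list(threshold = threshold, min_radius = min_radius,
                 circularity_cutoff = circularity_cutoff,
                 polarity = polarity, schedule = schedule),
            class = "scc_config")
}

#' @export
print.scc_config <- function(x, ...) {
  cat(sprintf("<scc_config> threshold %s, min_radius %s px, circularity %s, polarity %s\n",
              format(x$threshold), format(x$min_radius),
              format(x$circularity_cutoff), x$polarity))
  invisible(x)
}

#' Global binary threshold
#'
#' Foreground marks candidate cell pixels. With `dark_on_light` polarity a
#' pixel is foreground when strictly below the threshold; with
#' `light_on_dark`, strictly above. Pixels exactly at the threshold are
#' background under either polarity.
#'
#' @param img a [gray_image()] or numeric matrix in 0--255.
#' @param threshold intensity cutoff in `[0, 255]` (may be fractional, e.g.
#'   a threshold-factor multiple of the image mean).
#' @param polarity `"dark_on_light"` or `"light_on_dark"`.
#' @return A logical matrix (`TRUE` = foreground) of the same dimensions.
#' @export
binarize <- function(img, threshold, polarity = c("dark_on_light", "light_on_dark")) {
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255) stop("'threshold' must lie in [0, 255]")
  m <- if (polarity == "dark_on_light") img < threshold else img > threshold
  matrix(as.logical(m), nrow(img), ncol(img))
}

#' Morphological iterations for a threshold/MPI ratio
#'
#' @param threshold the configured intensity threshold.
#' @param mpi mean pixel intensity of the image (see
#'   [mean_pixel_intensity()]); must be positive.
#' @param schedule an [iteration_schedule()].
#' @return A positive integer; non-decreasing in `threshold / mpi`.
#' @export
iteration_count <- function(threshold, mpi, schedule = iteration_schedule()) {
  if (!is.finite(mpi) || mpi <= 0)
    stop("degenerate image: mean pixel intensity must be positive")
  ratio <- threshold / mpi
  schedule$iterations[[which(ratio < schedule$upper)[1]]]
}

#' Adaptive noise filter: morphological opening of the foreground
#'
#' Erodes the foreground `iterations` times with a 3x3 square structuring
#' element, then dilates it back the same number of times. Speckles smaller
#' than the element disappear; larger objects keep their approximate shape.
#' Pixels outside the image are treated as background, and the operation is
#' anti-extensive: output foreground is a subset of the input foreground.
#'
#' @param mask logical foreground mask from [binarize()].
#' @param iterations positive number of erosion (then dilation) passes.
#' @return A logical matrix of the same dimensions.
#' @export
morphological_filter <- function(mask, iterations = 1L) {
  if (iterations < 1L) stop("'iterations' must be positive")
  m <- mask
  for (i in seq_len(iterations)) m <- shift_erode(m)
  for (i in seq_len(iterations)) m <- shift_dilate(m)
  m
}

# 3x3 erosion/dilation by vectorized shifts; outside the image = background.
shift_nbhd <- function(m, f, pad) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  padded <- matrix(pad, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    out <- f(out, padded[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx])
  }
  out
}
shift_erode <- function(m) shift_nbhd(m, `&`, FALSE)
shift_dilate <- function(m) shift_nbhd(m, `|`, FALSE)
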
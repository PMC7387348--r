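#' Extract object contours from a binary mask
#'
#' Each 8-connected foreground component yields one contour record. Holes
#' inside a component are filled first, so the area is the zeroth-order
#' moment of the filled region (its pixel count) and the centroid is the
#' first moments divided by the area. Coordinates are 0-based `(x, y)`,
#' x = column, y = row, origin at the top-left pixel.
#'
#' @param mask logical foreground mask, typically the output of
#'   [morphological_filter()].
#' @return A list of contour records, each a list with elements `id`,
#'   `boundary` (perimeter points, n x 2 matrix of 0-based x,y), `area`,
#'   `centroid` (x, y), `xy` (filled-region pixel coordinates, n x 2,
#'   0-based), and placeholders `circularity`, `is_circular`, `cell_count`
#'   (`NA` until classified). The empty mask gives an empty list.
#' @export
extract_contours <- function(mask) {
  filled <- fill_holes(mask)
  lab <- label_components(filled, connectivity = 8L)
  n <- max(lab)
  if (n == 0L) return(list())
  h <- nrow(mask)
  lapply(seq_len(n), function(id) {
    pix <- which(lab == id)
    xy <- cbind(x = (pix - 1L) %/% h, y = (pix - 1L) %% h)  # 0-based
    list(id = id,
         boundary = component_boundary(lab, id),
         area = nrow(xy),
         centroid = c(x = mean(xy[, 1]), y = mean(xy[, 2])),
         xy = xy,
         circularity = NA_real_, is_circular = NA, cell_count = NA_integer_)
  })
}

#' Discard contours smaller than the minimum cell size
#'
#' The user's radius criterion is converted to an area cutoff
#' `pi * min_radius^2`; contours whose filled pixel-count area is below it
#' are dropped. Order is preserved.
#'
#' @param contours list from [extract_contours()].
#' @param min_radius minimum cell radius in pixels (> 0).
#' @return The retained sublist.
#' @export
area_filter <- function(contours, min_radius) {
  if (min_radius <= 0) stop("'min_radius' must be positive")
  cutoff <- pi * min_radius^2
  Filter(function(ct) ct$area >= cutoff, contours)
}

#' Circularity as the log-adjusted first Hu moment
#'
#' The first Hu invariant of a region is `eta20 + eta02`, the sum of its
#' second-order normalized central moments; it is invariant to translation,
#' scale and rotation and equals `1/(2*pi)` for an ideal disk. The returned
#' score is `-log10` of it: ~0.798 for a rasterized disk, lower for
#' elongated or fused shapes (a strongly fused pair of equal disks scores
#' below ~0.76).
#'
#' Moments are computed over the filled region's pixel centres with unit
#' weight per pixel — the same convention as the area filter.
#'
#' @param contour a contour record from [extract_contours()], or a logical
#'   matrix interpreted as a filled region.
#' @return The circularity score (dimensionless).
#' @export
hu_circularity <- function(contour) {
  if (is.matrix(contour) && is.logical(contour)) {
    w <- which(contour, arr.ind = TRUE)
    x <- w[, 2]; y <- w[, 1]
  } else {
    x <- contour$xy[, 1]; y <- contour$xy[, 2]
  }
  n <- length(x)
  if (n == 0L) stop("degenerate contour: zero area")
  mu20 <- sum((x - mean(x))^2)
  mu02 <- sum((y - mean(y))^2)
  h1 <- (mu20 + mu02) / n^2
  if (h1 <= 0) stop("degenerate contour: zero second moments")
  -log10(h1)
}

#' Split contours into circular and non-circular sets
#'
#' Computes (if missing) each contour's circularity and routes it by the
#' cutoff: scores at or above the cutoff are circular and each counts as
#' exactly one cell; the rest are candidate overlapping-cell contours whose
#' count is decided by the overlap classifier.
#'
#' @param contours list from [extract_contours()] (after [area_filter()]).
#' @param cutoff circularity cutoff (see [scc_config()]).
#' @return `list(circular = ..., non_circular = ...)`, both lists of contour
#'   records with `circularity` and `is_circular` filled in; circular
#'   records have `cell_count = 1`.
#' @export
classify_circularity <- function(contours, cutoff) {
  scored <- lapply(contours, function(ct) {
    if (is.na(ct$circularity)) ct$circularity <- hu_circularity(ct)
    ct$is_circular <- ct$circularity >= cutoff
    if (ct$is_circular) ct$cell_count <- 1L
    ct
  })
  list(circular = Filter(function(ct) ct$is_circular, scored),
       non_circular = Filter(function(ct) !ct$is_circular, scored))
}

contour_df <- function(contours) {
  if (length(contours) == 0L) {
    return(data.frame(contour_id = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area = numeric(0),
                      circularity = numeric(0), is_circular = logical(0),
                      cell_count = integer(0)))
  }
  data.frame(
    contour_id = vapply(contours, function(ct) ct$id, integer(1)),
    centroid_x = vapply(contours, function(ct) ct$centroid[["x"]], numeric(1)),
    centroid_y = vapply(contours, function(ct) ct$centroid[["y"]], numeric(1)),
    area = vapply(contours, function(ct) as.numeric(ct$area), numeric(1)),
    circularity = vapply(contours, function(ct) ct$circularity, numeric(1)),
    is_circular = vapply(contours, function(ct) ct$is_circular, logical(1)),
    cell_count = vapply(contours, function(ct) as.integer(ct$cell_count), integer(1))
  )
}
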
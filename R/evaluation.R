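#' Absolute count error between a reference and an automated method
#'
#' Per image, the absolute difference between the reference (e.g. manual or
#' ground-truth) count and the method count, plus their mean.
#'
#' @param reference,method equal-length aligned count vectors.
#' @param image_ids optional image identifiers (defaults to indices).
#' @return A list of class `error_report`: `per_image` data frame
#'   (`image_id`, `reference_count`, `method_count`, `abs_error`) and
#'   `mean_abs_error`.
#' @export
abs_error <- function(reference, method, image_ids = NULL) {
  if (length(reference) != length(method))
    stop("alignment error: 'reference' and 'method' must have equal length")
  if (is.null(image_ids)) image_ids <- as.character(seq_along(reference))
  per <- data.frame(image_id = image_ids,
                    reference_count = reference, method_count = method,
                    abs_error = abs(reference - method),
                    stringsAsFactors = FALSE)
  structure(list(per_image = per, mean_abs_error = mean(per$abs_error)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %d images, mean absolute error %.3f\n",
              nrow(x$per_image), x$mean_abs_error))
  invisible(x)
}

#' Match detected cells to reference cells by centroid distance
#'
#' Greedy one-to-one nearest-neighbour matching: all reference/detected
#' pairs within `tol` pixels are sorted by distance (ties broken by
#' lexicographic coordinates, so the result is order-independent) and
#' accepted closest-first while both points are unmatched. Unmatched
#' detections are false positives (counted by the method but not the
#' reference); unmatched reference points are false negatives.
#'
#' @param reference,detected n x 2 matrices (or data frames) of (x, y)
#'   centroids.
#' @param tol matching tolerance in pixels (> 0); default 10, the standard
#'   minimum cell radius.
#' @return `list(matched, false_positives, false_negatives)`; `matched` is
#'   a data frame of (ref, det, distance) index pairs.
#' @export
match_detections <- function(reference, detected, tol = 10) {
  if (tol <= 0) stop("'tol' must be positive")
  ref <- as.matrix(reference); det <- as.matrix(detected)
  nr <- nrow(ref); nd <- nrow(det)
  matched <- data.frame(ref = integer(0), det = integer(0), distance = numeric(0))
  if (nr > 0L && nd > 0L) {
    dx <- outer(ref[, 1], det[, 1], `-`); dy <- outer(ref[, 2], det[, 2], `-`)
    dist <- sqrt(dx^2 + dy^2)
    cand <- which(dist <= tol, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      dd <- dist[cand]
      ord <- order(dd, ref[cand[, 1], 1], ref[cand[, 1], 2],
                   det[cand[, 2], 1], det[cand[, 2], 2])
      used_r <- logical(nr); used_d <- logical(nd)
      keep <- integer(0)
      for (i in ord) {
        r <- cand[i, 1]; d <- cand[i, 2]
        if (!used_r[r] && !used_d[d]) {
          used_r[r] <- TRUE; used_d[d] <- TRUE
          keep <- c(keep, i)
        }
      }
      matched <- data.frame(ref = cand[keep, 1], det = cand[keep, 2],
                            distance = dist[cand[keep, , drop = FALSE]])
    }
  }
  list(matched = matched,
       false_positives = nd - nrow(matched),
       false_negatives = nr - nrow(matched))
}

#' Ordinary least-squares regression of method counts on reference counts
#'
#' Fits `method = slope * reference + intercept` and reports the two-sided
#' p-value for the slope differing from zero.
#'
#' @param reference,method aligned count vectors, `n >= 3`.
#' @return A list of class `regression_fit`: `slope`, `intercept`,
#'   `p_value`, `n`.
#' @export
fit_counts_regression <- function(reference, method) {
  if (length(reference) != length(method))
    stop("alignment error: 'reference' and 'method' must have equal length")
  if (length(reference) < 3L) stop("need n >= 3 for a regression fit")
  if (stats::var(reference) == 0)
    stop("degenerate fit: reference counts have zero variance")
  fit <- stats::lm(method ~ reference)
  co <- summary(fit)$coefficients
  structure(list(slope = unname(co["reference", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 p_value = unname(co["reference", "Pr(>|t|)"]),
                 n = length(reference)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.3fx %+.2f (n = %d, p = %.3g)\n",
              x$slope, x$intercept, x$n, x$p_value))
  invisible(x)
}
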
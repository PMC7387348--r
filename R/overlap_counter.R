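#' Normalize a contour into a fixed-size binary patch
#'
#' Crops the filled contour's bounding box (only the contour's own pixels —
#' neighbouring objects are masked out), pads it by a fixed fraction of its
#' larger side, centres it on a square canvas and resizes onto the fixed
#' grid with bilinear interpolation, re-binarizing at 0.5. The result is
#' translation-invariant by construction and scale-normalized up to
#' resampling error.
#'
#' @param contour contour record from [extract_contours()].
#' @param size side of the square output grid (default 64).
#' @param pad_frac padding as a fraction of the larger bounding-box side.
#' @return A `size x size` logical matrix with attributes
#'   `source_contour_id` and `scale_factor`.
#' @export
make_patch <- function(contour, size = 64L, pad_frac = 0.1) {
  xy <- contour$xy
  x0 <- min(xy[, 1]); y0 <- min(xy[, 2])
  bw <- max(xy[, 1]) - x0 + 1L
  bh <- max(xy[, 2]) - y0 + 1L
  side <- max(bw, bh)
  pad <- max(1L, round(pad_frac * side))
  canvas <- side + 2L * pad
  local <- matrix(FALSE, canvas, canvas)             # [y, x]
  oy <- pad + (canvas - 2L * pad - bh) %/% 2L
  ox <- pad + (canvas - 2L * pad - bw) %/% 2L
  local[cbind(xy[, 2] - y0 + 1L + oy, xy[, 1] - x0 + 1L + ox)] <- TRUE
  res <- EBImage::resize(EBImage::Image(t(local) * 1), w = size, h = size,
                         filter = "bilinear")
  patch <- t(EBImage::imageData(res)) > 0.5
  attr(patch, "source_contour_id") <- contour$id
  attr(patch, "scale_factor") <- size / canvas
  patch
}

patch_rows <- function(patches) {
  if (is.matrix(patches) && !is.list(patches) && !is.logical(patches[[1]]))
    return(patches)
  if (is.matrix(patches) && is.logical(patches)) patches <- list(patches)
  do.call(rbind, lapply(patches, function(p) as.numeric(p)))
}

overlap_arch <- function(input)
  nn_architecture(input, conv1 = c(5L, 12L), conv2 = c(3L, 24L), hidden = 96L)

#' Train the overlapping-cell classifier
#'
#' Fits a small convolutional network (2 convolution + max-pool blocks, a
#' dense layer and a 4-way softmax on 64 x 64 binary input) that maps a
#' normalized contour patch to the number of cells it contains, classes
#' 1--4 with 4 meaning "4 or more". By default training patches are drawn
#' from the synthetic overlap generator ([make_overlap_patch()]): fused
#' disk clusters with jittered radii, labelled by construction.
#'
#' @param n_per_class synthetic patches generated per class when `patches`
#'   is `NULL`.
#' @param seed integer seed; training is fully reproducible given the seed.
#' @param epochs training epochs.
#' @param patches optional list of logical patch matrices (or an n x 4096
#'   numeric matrix) to train on instead of generated ones.
#' @param labels integer cell counts (1--4) matching `patches`.
#' @param lr,batch Adam learning rate and minibatch size.
#' @param holdout_frac fraction per class held out to report accuracy.
#' @return An object of class `overlap_model` with the learned parameters,
#'   class labels, training metadata and held-out accuracy (overall and per
#'   class).
#' @export
train_overlap_model <- function(n_per_class = 400L, seed = 1L, epochs = 35L,
                                patches = NULL, labels = NULL, lr = 1e-3,
                                batch = 64L, holdout_frac = 0.15) {
  classes <- 1:4
  if (is.null(patches)) {
    gen_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                  n_per_class * length(classes)))
    labels <- rep(classes, each = n_per_class)
    patches <- lapply(seq_along(labels), function(i)
      make_overlap_patch(labels[i], seed = gen_seeds[i])$patch)
  }
  labels <- as.integer(labels)
  if (length(patches) != length(labels)) stop("'patches' and 'labels' lengths differ")
  tab <- table(factor(labels, levels = classes))
  if (sum(tab > 0L) < 2L)
    stop("insufficient data: training requires at least two classes")
  if (any(tab < 20L))
    stop("insufficient data: need at least 20 patches per class, got ",
         paste(tab, collapse = "/"))

  X <- patch_rows(patches)
  specs <- overlap_arch(as.integer(sqrt(ncol(X))))
  with_local_seed(seed + 1L, {
    holdout <- unlist(lapply(classes, function(k) {
      ik <- which(labels == k)
      sample(ik, max(1L, round(holdout_frac * length(ik))))
    }))
    train_idx <- setdiff(seq_along(labels), holdout)
    params <- nn_init(specs)
    state <- adam_init(params)
    perms <- dihedral_perms(as.integer(sqrt(ncol(X))))
    t_step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      lr_ep <- lr / 2^findInterval(ep / epochs, c(0.5, 0.8))
      for (s in seq(1L, length(ord), by = batch)) {
        ii <- ord[s:min(s + batch - 1L, length(ord))]
        Xb <- X[ii, , drop = FALSE]
        # dihedral augmentation: a random square symmetry per sample
        pk <- sample.int(8L, length(ii), replace = TRUE)
        for (q in which(pk > 1L)) Xb[q, ] <- Xb[q, perms[[pk[q]]]]
        fw <- nn_forward(Xb, params, specs, keep_cache = TRUE)
        ls <- xent_loss(fw$logits, labels[ii])
        grads <- nn_backward(ls$dlogits, fw$caches, params, specs, length(ii))
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, t_step, lr = lr_ep)
        params <- upd$params; state <- upd$state
      }
    }
  })
  pred_hold <- nn_predict(X[holdout, , drop = FALSE], params, specs, classes)
  truth_hold <- labels[holdout]
  per_class <- vapply(classes, function(k) {
    ik <- truth_hold == k
    if (!any(ik)) return(NA_real_)
    mean(pred_hold[ik] == k)
  }, numeric(1))
  structure(list(
    params = params,
    architecture = "avgpool2-conv5x5x12-maxpool2-conv3x3x24-maxpool2-dense96-softmax4",
    input_size = as.integer(sqrt(ncol(X))),
    classes = classes,
    seed = seed, epochs = epochs,
    n_patches = as.integer(tab),
    holdout_accuracy = list(overall = mean(pred_hold == truth_hold),
                            per_class = stats::setNames(per_class, classes)),
    version = "sccount-overlap-1"
  ), class = "overlap_model")
}

# Prediction averages class probabilities over the 8 square symmetries of
# each patch (deterministic test-time augmentation): the cell count is
# invariant under them, and averaging markedly stabilizes the 3-vs-4
# boundary.
nn_predict <- function(X, params, specs, classes) {
  perms <- dihedral_perms(as.integer(sqrt(ncol(X))))
  probs <- 0
  for (pm in perms) {
    logits <- nn_forward(X[, pm, drop = FALSE], params, specs)$logits
    probs <- probs + softmax_probs(logits)
  }
  classes[max.col(probs, ties.method = "first")]
}

#' @export
print.overlap_model <- function(x, ...) {
  cat("<overlap_model>", x$architecture, "\n")
  cat(sprintf("  classes %s; trained %d epochs, seed %d, patches %s\n",
              paste(x$classes, collapse = "/"), x$epochs, x$seed,
              paste(x$n_patches, collapse = "/")))
  cat(sprintf("  held-out accuracy %.3f (per class: %s)\n",
              x$holdout_accuracy$overall,
              paste(sprintf("%.2f", x$holdout_accuracy$per_class), collapse = ", ")))
  invisible(x)
}

#' Predict cell counts for patches
#'
#' @param object an `overlap_model`.
#' @param patches one logical patch matrix, a list of them, or an n x 4096
#'   numeric matrix.
#' @param ... unused.
#' @return Integer vector of predicted counts (one per patch).
#' @export
predict.overlap_model <- function(object, patches, ...) {
  X <- patch_rows(patches)
  specs <- overlap_arch(object$input_size)
  as.integer(nn_predict(X, object$params, specs, object$classes))
}

#' Count cells inside one non-circular contour patch
#'
#' Degenerate patches (< 20 foreground pixels) are counted as a single cell
#' with a warning.
#'
#' @param model a trained [train_overlap_model()] object.
#' @param patch a logical patch from [make_patch()].
#' @return Integer count in the model's class set.
#' @export
count_in_contour <- function(model, patch) {
  if (!inherits(model, "overlap_model"))
    stop("'model' is not a trained overlap model")
  if (sum(patch) < 20L) {
    warning("degenerate patch (<20 foreground pixels); counting as 1 cell")
    return(1L)
  }
  predict(model, patch)
}

#' Deterministic area-based fallback count
#'
#' Used when no overlap model is available: the contour area is divided by
#' the expected single-cell area `pi * min_radius^2` inflated by a packing
#' constant `k` (default 1.5, since fused cells share area), rounded, and
#' floored at 1.
#'
#' @param contour contour record with positive area.
#' @param min_radius the configured minimum cell radius (pixels).
#' @param k packing constant.
#' @return Integer count >= 1.
#' @export
count_in_contour_fallback <- function(contour, min_radius, k = 1.5) {
  if (contour$area <= 0) stop("contour area must be positive")
  max(1L, as.integer(round(contour$area / (pi * min_radius^2 * k))))
}

#' Save / load an overlap model
#'
#' The file carries a format version; loading refuses a mismatched version
#' rather than silently misinterpreting parameters.
#'
#' @param model an `overlap_model`.
#' @param path file path.
#' @return `write_overlap_model` returns `path` invisibly;
#'   `read_overlap_model` returns the model.
#' @export
write_overlap_model <- function(model, path) {
  if (!inherits(model, "overlap_model")) stop("not an overlap model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_overlap_model
#' @export
read_overlap_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "overlap_model") || !identical(m$version, "sccount-overlap-1"))
    stop("'", path, "' is not a compatible overlap model file")
  m
}
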
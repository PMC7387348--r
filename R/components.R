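# Connected-component labelling and hole filling on logical masks.
# 8-connectivity for objects, 4-connectivity for background (the standard
# dual pairing, which keeps object and hole topology consistent).

#' Label connected foreground components
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default, objects) or 4 (background/holes).
#' @return Integer matrix of labels; 0 is background. Labels are assigned in
#'   raster order of each component's first pixel, so labelling is
#'   deterministic.
#' @keywords internal
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  compact <- integer(h * w)
  compact[idx] <- seq_along(idx)

  offsets <- list(c(1L, 0L), c(0L, 1L))               # down, right
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    dy <- offsets[[k]][1]; dx <- offsets[[k]][2]
    ys <- seq_len(h - dy)
    xs <- if (dx >= 0L) seq_len(w - dx) else seq.int(1L - dx, w)
    a <- mask[ys, xs, drop = FALSE] & mask[ys + dy, xs + dx, drop = FALSE]
    hit <- which(a)
    if (length(hit) == 0L) next
    ar <- arrayInd(hit, dim(a))
    y0 <- ar[, 1] + ys[1] - 1L; x0 <- ar[, 2] + xs[1] - 1L
    e1 <- (x0 - 1L) * h + y0
    e2 <- (x0 + dx - 1L) * h + y0 + dy
    edges[[k]] <- cbind(compact[e1], compact[e2])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  # relabel so component ids follow raster order of first occurrence
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[idx] <- relab[memb]
  lab
}

#' Fill holes in a foreground mask
#'
#' Background regions (4-connected) that do not touch the image border are
#' enclosed by foreground and become foreground. Internal holes can appear
#' when staining gradients push a few interior pixels past the threshold.
#'
#' @param mask logical matrix.
#' @return Logical matrix with holes filled.
#' @keywords internal
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  if (max(bg) == 0L) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

# Boundary of one labelled component: foreground pixels with at least one
# 8-neighbour outside the component (or on the image border), ordered by a
# Moore trace so points follow the perimeter.
component_boundary <- function(lab, id) {
  sel <- lab == id
  h <- nrow(sel); w <- ncol(sel)
  inner <- matrix(FALSE, h, w)
  if (h > 2L && w > 2L)
    inner[2:(h - 1L), 2:(w - 1L)] <-
      sel[2:(h-1L), 2:(w-1L)] & sel[1:(h-2L), 2:(w-1L)] & sel[3:h, 2:(w-1L)] &
      sel[2:(h-1L), 1:(w-2L)] & sel[2:(h-1L), 3:w] &
      sel[1:(h-2L), 1:(w-2L)] & sel[1:(h-2L), 3:w] &
      sel[3:h, 1:(w-2L)] & sel[3:h, 3:w]
  bd <- which(sel & !inner, arr.ind = TRUE)
  ord <- order(atan2(bd[, 1] - mean(bd[, 1]), bd[, 2] - mean(bd[, 2])),
               bd[, 1], bd[, 2])
  cbind(x = bd[ord, 2] - 1L, y = bd[ord, 1] - 1L)  # 0-based (x, y)
}
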
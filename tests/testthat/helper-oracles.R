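# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops and outer() arithmetic.

# Rasterize a filled disk on an n x n grid, 1-based centre (cx, cy).
raster_disk <- function(n, cx, cy, r) {
  outer(seq_len(n), seq_len(n), function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

# Log-adjusted first Hu moment straight from the definition.
hu_oracle <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  x <- w[, 2]; y <- w[, 1]; n <- length(x)
  mu20 <- sum((x - mean(x))^2)
  mu02 <- sum((y - mean(y))^2)
  -log10((mu20 + mu02) / n^2)
}

# 3x3 erosion/dilation with nested loops; outside the image is background.
erode_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    keep <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      v <- ii >= 1 && ii <= h && jj >= 1 && jj <= w && m[ii, jj]
      if (!v) keep <- FALSE
    }
    out[i, j] <- keep
  }
  out
}

dilate_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    hit <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && m[ii, jj]) hit <- TRUE
    }
    out[i, j] <- hit
  }
  out
}

opening_oracle <- function(m, iterations) {
  for (i in seq_len(iterations)) m <- erode_oracle(m)
  for (i in seq_len(iterations)) m <- dilate_oracle(m)
  m
}

# 8-connected component sizes by stack-based flood fill.
component_sizes_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  sizes <- integer(0)
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE; sz <- 0L
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      sz <- sz + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

# Fill holes by flooding 4-connected background from the border; anything
# unreached is a hole. Matches the package's filled-region convention.
fill_holes_for_test <- function(mask) {
  filled <- mask
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  stack <- list()
  for (i in seq_len(h)) for (j in c(1L, w)) if (!mask[i, j]) stack[[length(stack) + 1L]] <- c(i, j)
  for (j in seq_len(w)) for (i in c(1L, h)) if (!mask[i, j]) stack[[length(stack) + 1L]] <- c(i, j)
  while (length(stack) > 0L) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    if (seen[p[1], p[2]]) next
    seen[p[1], p[2]] <- TRUE
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- p[1] + d[1]; jj <- p[2] + d[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && !mask[ii, jj] && !seen[ii, jj])
        stack[[length(stack) + 1L]] <- c(ii, jj)
    }
  }
  filled[!mask & !seen] <- TRUE
  filled
}

# Optimal bipartite matching under a distance cap, by exhaustive recursion
# (reference sets kept small). Returns the maximum number of matched pairs.
optimal_match_oracle <- function(ref, det, tol) {
  nr <- nrow(ref); nd <- nrow(det)
  if (nr == 0L || nd == 0L) return(0L)
  dist <- sqrt(outer(ref[, 1], det[, 1], `-`)^2 + outer(ref[, 2], det[, 2], `-`)^2)
  ok <- dist <= tol
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nr - i + 1L) <= best) return()
    if (i > nr) { best <<- max(best, count); return() }
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1L, used, count + 1L)
      used[j] <- FALSE
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, logical(nd), 0L)
  best
}
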
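# Minimal convolutional-network machinery for the overlap classifier.
#
# Feature maps are stored one sample per row as n x (H*W*C) matrices; each
# channel is a column-major H x W plane, so the flat index of (row y, col x,
# channel c), all 1-based, is (c-1)*H*W + (x-1)*H + y. Convolutions use
# precomputed im2col index tables; all heavy lifting is BLAS matrix algebra.
# Gradients are checked against numerical differentiation in the test suite.

conv_spec <- function(H, W, C, k, filters) {
  Ho <- H - k + 1L; Wo <- W - k + 1L
  P <- Ho * Wo
  io <- rep.int(seq_len(Ho), Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  off <- expand.grid(a = seq_len(k), b = seq_len(k), c = seq_len(C))
  K <- nrow(off)
  idx <- matrix(0L, P, K)
  for (kk in seq_len(K)) {
    a <- off$a[kk]; b <- off$b[kk]; cc <- off$c[kk]
    idx[, kk] <- (cc - 1L) * H * W + (jo + b - 2L) * H + (io + a - 1L)
  }
  list(type = "conv", H = H, W = W, C = C, k = k, filters = filters,
       Ho = Ho, Wo = Wo, P = P, K = K, idx = idx)
}

pool_spec <- function(H, W, C, s, op = c("max", "avg")) {
  op <- match.arg(op)
  Ho <- H %/% s; Wo <- W %/% s
  io <- rep.int(seq_len(Ho), Wo * C)
  jo <- rep(rep(seq_len(Wo), each = Ho), C)
  cc <- rep(seq_len(C), each = Ho * Wo)
  corners <- vector("list", s * s)
  m <- 0L
  for (b in seq_len(s)) for (a in seq_len(s)) {
    m <- m + 1L
    corners[[m]] <- (cc - 1L) * H * W + ((jo - 1L) * s + b - 1L) * H +
      ((io - 1L) * s + a)
  }
  list(type = paste0(op, "pool"), H = H, W = W, C = C, s = s,
       Ho = Ho, Wo = Wo, corners = corners)
}

dense_spec <- function(d_in, d_out, relu = TRUE)
  list(type = "dense", d_in = d_in, d_out = d_out, relu = relu)

conv_forward <- function(X, Wt, b, spec) {
  n <- nrow(X)
  cols <- matrix(X[, as.vector(spec$idx), drop = FALSE], n * spec$P, spec$K)
  Z <- cols %*% Wt
  Z <- Z + rep(b, each = nrow(Z))
  A <- Z * (Z > 0)                                   # ReLU
  list(out = matrix(A, n, spec$P * spec$filters), cols = cols, Z = Z)
}

conv_backward <- function(dY, cache, Wt, spec, n) {
  dA <- matrix(dY, n * spec$P, spec$filters)
  dZ <- dA * (cache$Z > 0)
  dW <- crossprod(cache$cols, dZ)
  db <- colSums(dZ)
  dcols <- dZ %*% t(Wt)                              # (n*P) x K
  dcols <- matrix(dcols, n, spec$P * spec$K)
  dX <- matrix(0, n, spec$H * spec$W * spec$C)
  for (kk in seq_len(spec$K)) {
    blk <- ((kk - 1L) * spec$P + 1L):(kk * spec$P)
    cols_k <- spec$idx[, kk]
    dX[, cols_k] <- dX[, cols_k] + dcols[, blk]
  }
  list(dW = dW, db = db, dX = dX)
}

pool_forward <- function(X, spec) {
  if (spec$type == "avgpool") {
    out <- X[, spec$corners[[1]], drop = FALSE]
    for (m in 2:length(spec$corners)) out <- out + X[, spec$corners[[m]], drop = FALSE]
    return(list(out = out / length(spec$corners)))
  }
  best <- X[, spec$corners[[1]], drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (m in 2:length(spec$corners)) {
    a <- X[, spec$corners[[m]], drop = FALSE]
    upd <- a > best
    arg[upd] <- m
    best[upd] <- a[upd]
  }
  list(out = best, arg = arg)
}

pool_backward <- function(dY, cache, spec) {
  dX <- matrix(0, nrow(dY), spec$H * spec$W * spec$C)
  if (spec$type == "avgpool") {
    share <- dY / length(spec$corners)
    for (m in seq_along(spec$corners)) dX[, spec$corners[[m]]] <- share
    return(dX)
  }
  for (m in seq_along(spec$corners)) {
    sel <- cache$arg == m
    if (any(sel)) dX[, spec$corners[[m]]] <- dY * sel
  }
  dX
}

dense_forward <- function(X, Wt, b, spec) {
  Z <- X %*% Wt + rep(b, each = nrow(X))
  list(out = if (spec$relu) Z * (Z > 0) else Z, Z = Z, X = X)
}

dense_backward <- function(dY, cache, Wt, spec) {
  dZ <- if (spec$relu) dY * (cache$Z > 0) else dY
  list(dW = crossprod(cache$X, dZ), db = colSums(dZ), dX = dZ %*% t(Wt))
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy and gradient w.r.t. logits for 1-based integer labels.
xent_loss <- function(logits, labels) {
  p <- softmax_probs(logits)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), labels)]
  dlogits <- p
  dlogits[cbind(seq_len(n), labels)] <- picked - 1
  list(loss = -mean(log(pmax(picked, 1e-12))), dlogits = dlogits / n)
}

nn_architecture <- function(input = 64L, conv1 = c(5L, 8L), conv2 = c(3L, 16L),
                            hidden = 64L, classes = 4L) {
  specs <- list()
  specs[[1]] <- pool_spec(input, input, 1L, 2L, "avg")          # 64 -> 32
  h <- input %/% 2L
  specs[[2]] <- conv_spec(h, h, 1L, conv1[1], conv1[2])         # 32 -> 28 x 8
  h <- h - conv1[1] + 1L
  specs[[3]] <- pool_spec(h, h, conv1[2], 2L, "max")            # 28 -> 14
  h <- h %/% 2L
  specs[[4]] <- conv_spec(h, h, conv1[2], conv2[1], conv2[2])   # 14 -> 12 x 16
  h <- h - conv2[1] + 1L
  specs[[5]] <- pool_spec(h, h, conv2[2], 2L, "max")            # 12 -> 6
  h <- h %/% 2L
  specs[[6]] <- dense_spec(h * h * conv2[2], hidden, relu = TRUE)
  specs[[7]] <- dense_spec(hidden, classes, relu = FALSE)
  specs
}

nn_init <- function(specs) {
  lapply(specs, function(sp) {
    if (sp$type == "conv") {
      fan_in <- sp$K
      list(W = matrix(stats::rnorm(sp$K * sp$filters, 0, sqrt(2 / fan_in)),
                      sp$K, sp$filters),
           b = rep(0, sp$filters))
    } else if (sp$type == "dense") {
      list(W = matrix(stats::rnorm(sp$d_in * sp$d_out, 0, sqrt(2 / sp$d_in)),
                      sp$d_in, sp$d_out),
           b = rep(0, sp$d_out))
    } else NULL
  })
}

nn_forward <- function(X, params, specs, keep_cache = FALSE) {
  caches <- vector("list", length(specs))
  out <- X
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    res <- switch(sp$type,
                  conv = conv_forward(out, params[[i]]$W, params[[i]]$b, sp),
                  maxpool = pool_forward(out, sp),
                  avgpool = pool_forward(out, sp),
                  dense = dense_forward(out, params[[i]]$W, params[[i]]$b, sp))
    out <- res$out
    if (keep_cache) caches[[i]] <- res
  }
  list(logits = out, caches = caches)
}

nn_backward <- function(dlogits, caches, params, specs, n) {
  grads <- vector("list", length(specs))
  d <- dlogits
  for (i in rev(seq_along(specs))) {
    sp <- specs[[i]]
    if (sp$type == "dense") {
      g <- dense_backward(d, caches[[i]], params[[i]]$W, sp)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      d <- g$dX
    } else if (sp$type == "conv") {
      g <- conv_backward(d, caches[[i]], params[[i]]$W, sp, n)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      d <- g$dX
    } else {
      if (i == 1L) break                           # no parameters below input
      d <- pool_backward(d, caches[[i]], sp)
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

adam_step <- function(params, grads, state, t, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    g <- grads[[i]]
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * g$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$db
    st$vb <- beta2 * st$vb + (1 - beta2) * g$db^2
    mhatW <- st$mW / (1 - beta1^t); vhatW <- st$vW / (1 - beta2^t)
    mhatb <- st$mb / (1 - beta1^t); vhatb <- st$vb / (1 - beta2^t)
    params[[i]]$W <- params[[i]]$W - lr * mhatW / (sqrt(vhatW) + eps)
    params[[i]]$b <- params[[i]]$b - lr * mhatb / (sqrt(vhatb) + eps)
    state[[i]] <- st
  }
  list(params = params, state = state)
}

# Index permutations of a flattened s x s plane realizing the 8 symmetries
# of the square (identity, rotations, reflections). Applying one to a patch
# row is a label-preserving augmentation for shape classification.
dihedral_perms <- function(s) {
  base <- matrix(seq_len(s * s), s, s)               # [y, x] column-major
  variants <- list(base, t(base), base[s:1, ], base[, s:1],
                   t(base)[s:1, ], t(base)[, s:1],
                   base[s:1, s:1], t(base)[s:1, s:1])
  lapply(variants, as.vector)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
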
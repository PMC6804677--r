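# Primitive differentiable layers for the video classifier. Tensors are
# numeric arrays [channels, time, height, width, batch]; convolutions are
# evaluated as a sum of BLAS matrix products over kernel offsets, which is
# fast in plain R at the network's feature-map sizes. Every layer returns a
# forward value plus the cache its backward pass needs; backward passes are
# verified against numerical gradients in the test suite.

.truncNorm <- function(n, sd = 0.05, trunc = 2) {
  # inverse-CDF sampling restricted to +/- trunc standard deviations
  lo <- stats::pnorm(-trunc); hi <- stats::pnorm(trunc)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

.convOutDim <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1L

# W: array [cOut, cIn, kt, kh, kw]; b: length cOut or NULL. The heavy
# lifting (im2col + BLAS product, and the transposed products for the
# backward pass) lives in compiled code (src/conv.cpp).
.convFwd <- function(X, W, b = NULL, stride = c(1L, 1L, 1L), pad = c(0L, 0L, 0L)) {
  Y <- .conv5dForward(X, W, b, as.integer(stride), as.integer(pad))
  list(Y = Y, cache = list(X = X, W = W, hasBias = !is.null(b),
                           stride = as.integer(stride), pad = as.integer(pad)))
}

.convBwd <- function(cache, dY) {
  out <- .conv5dBackward(cache$X, cache$W, dY, cache$stride, cache$pad,
                         cache$hasBias)
  list(dX = out$dX, dW = out$dW, db = out$db)
}

.bnFwd <- function(X, p, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(d[1], prod(d[-1]))
  if (train) {
    mu <- rowMeans(Xm)
    xc <- Xm - mu
    v <- rowMeans(xc^2)
    ivar <- 1 / sqrt(v + eps)
    xhat <- xc * ivar
    p$rm <- momentum * p$rm + (1 - momentum) * mu
    p$rv <- momentum * p$rv + (1 - momentum) * v
  } else {
    ivar <- 1 / sqrt(p$rv + eps)
    xhat <- (Xm - p$rm) * ivar
  }
  Y <- p$gamma * xhat + p$beta
  dim(Y) <- d
  list(Y = Y, cache = list(xhat = xhat, ivar = ivar, gamma = p$gamma, d = d,
                           train = train),
       state = list(rm = p$rm, rv = p$rv))
}

.bnBwd <- function(cache, dY) {
  d <- cache$d
  dYm <- dY; dim(dYm) <- c(d[1], prod(d[-1]))
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  dxhat <- cache$gamma * dYm
  if (cache$train) {
    dX <- cache$ivar *
      (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dX <- cache$ivar * dxhat
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.reluFwd <- function(X) list(Y = pmax(X, 0), cache = X > 0)
.reluBwd <- function(cache, dY) dY * cache

# 2x2x2 max pooling with stride 2; odd extents drop the trailing slice.
.poolFwd <- function(X) {
  d <- dim(X)
  if (d[2] < 2 || d[3] < 2 || d[4] < 2) stop("non-poolable extent (< 2)")
  o <- d[2:4] %/% 2L
  Y <- NULL
  slices <- vector("list", 8)
  k <- 0L
  for (dt in 0:1) for (dy in 0:1) for (dx in 0:1) {
    k <- k + 1L
    s <- X[, seq(1L + dt, by = 2L, length.out = o[1]),
             seq(1L + dy, by = 2L, length.out = o[2]),
             seq(1L + dx, by = 2L, length.out = o[3]), , drop = FALSE]
    slices[[k]] <- s
    Y <- if (is.null(Y)) s else pmax(Y, s)
  }
  list(Y = Y, cache = list(slices = slices, d = d, o = o))
}

.poolBwd <- function(cache, dY) {
  d <- cache$d; o <- cache$o
  Ymax <- Reduce(pmax, cache$slices)
  dX <- array(0, d)
  remaining <- array(TRUE, dim(dY))
  k <- 0L
  for (dt in 0:1) for (dy in 0:1) for (dx in 0:1) {
    k <- k + 1L
    hit <- (cache$slices[[k]] == Ymax) & remaining
    remaining <- remaining & !hit
    g <- dY * hit
    ti <- seq(1L + dt, by = 2L, length.out = o[1])
    yi <- seq(1L + dy, by = 2L, length.out = o[2])
    xi <- seq(1L + dx, by = 2L, length.out = o[3])
    dX[, ti, yi, xi, ] <- dX[, ti, yi, xi, , drop = FALSE] + g
  }
  dX
}

.fcFwd <- function(X, W, b) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(prod(d[-length(d)]), d[length(d)])
  list(Y = W %*% Xm + b, cache = list(Xm = Xm, W = W, d = d))
}

.fcBwd <- function(cache, dY) {
  dW <- dY %*% t(cache$Xm)
  db <- rowSums(dY)
  dX <- t(cache$W) %*% dY
  dim(dX) <- cache$d
  list(dX = dX, dW = dW, db = db)
}

.dropoutFwd <- function(X, rate, train) {
  if (!train || rate == 0) return(list(Y = X, cache = NULL))
  keep <- 1 - rate
  mask <- (array(stats::runif(length(X)), dim(X)) < keep) / keep
  list(Y = X * mask, cache = mask)
}

.dropoutBwd <- function(cache, dY) if (is.null(cache)) dY else dY * cache

# Softmax + cross-entropy on logits Z (classes x n); labels in 1..nClasses.
.softmaxCE <- function(Z, labels = NULL) {
  Zs <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Zs)
  P <- sweep(E, 2, colSums(E), "/")
  if (is.null(labels)) return(list(P = P))
  n <- ncol(Z)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  Y <- matrix(0, nrow(Z), n)
  Y[idx] <- 1
  list(P = P, loss = loss, dZ = (P - Y) / n)
}

# channel concatenation: [A; B] along dim 1
.catChannels <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, c(da[1] + db[1], da[-1]))
  out[seq_len(da[1]), , , , ] <- A
  out[da[1] + seq_len(db[1]), , , , ] <- B
  out
}

.splitChannels <- function(dY, cA) {
  list(dA = dY[seq_len(cA), , , , , drop = FALSE],
       dB = dY[-seq_len(cA), , , , , drop = FALSE])
}

# Recursive walk over a nested parameter list, applying f to numeric leaves
# of corresponding structures. Used for Adam updates and gradient algebra.
.mapLeaves <- function(f, a, b = NULL, c3 = NULL) {
  if (is.list(a)) {
    keys <- if (is.null(names(a))) seq_along(a) else names(a)
    out <- a
    for (nm in keys)
      out[[nm]] <- .mapLeaves(f, a[[nm]],
                              if (is.null(b)) NULL else b[[nm]],
                              if (is.null(c3)) NULL else c3[[nm]])
    out
  } else {
    f(a, b, c3)
  }
}
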
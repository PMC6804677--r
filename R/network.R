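# Densely connected pseudo-3D video classifier.
#
# Architecture: a plain 1x7x7 spatial stem convolution (stride 2) and a
# plain 9x1x1 temporal stem convolution (stride 3, "same"-style padding),
# then a series of densely connected spatio-temporal blocks. Each block is
#   m' = Max[ Conv_t(Conv_s(m) (+) m) (+) (Conv_s(m) (+) m) ]
# where Conv_s / Conv_t are (batch norm -> ReLU -> 1x3x3 / 3x1x1
# convolution, stride 1, growth-rate k output channels), (+) is channel
# concatenation and Max is 2x2x2 stride-2 max pooling, so every block adds
# exactly 2k channels and halves every extent. Between two chosen blocks an
# extra 3x1x1 stride-1 unpadded convolution trims the temporal extent so
# that time and space reach 1x1x1 together; dropout, a fully connected
# layer and softmax produce the two class probabilities.

#' Network configuration
#'
#' Shape-checked hyperparameters of the densely connected P3D classifier.
#' The full-scale default takes 2 x 120 x 64 x 64 videos through stems
#' (-> 16 x 40 x 32 x 32), five dense blocks with growth rate k = 8 and a
#' temporal trim after block 2 (-> 8 x 8 x 8), ending at 1 x 1 x 1 before
#' the fully connected layer.
#'
#' @param inputShape c(channels, frames, height, width).
#' @param growthRate dense growth rate k (default 8).
#' @param stemChannels output channels of the spatial and temporal stems.
#' @param nBlocks number of dense blocks (default 5).
#' @param midConvAfter index of the block after which the unpadded 3x1x1
#'   temporal trim convolution is inserted; \code{NA} for none.
#' @param dropout dropout rate before the fully connected layer.
#' @param nClasses number of output classes (default 2).
#' @return a \code{p3dConfig} list with the validated shape trace attached.
#' @seealso \code{\link{networkShapes}}, \code{\link{buildNetwork}}
#' @export
p3dConfig <- function(inputShape = c(2L, 120L, 64L, 64L), growthRate = 8L,
                      stemChannels = c(16L, 16L), nBlocks = 5L,
                      midConvAfter = 2L, dropout = 0.5, nClasses = 2L) {
  cfg <- list(inputShape = as.integer(inputShape),
              growthRate = as.integer(growthRate),
              stemChannels = as.integer(stemChannels),
              nBlocks = as.integer(nBlocks),
              midConvAfter = if (is.na(midConvAfter)) NA_integer_
                             else as.integer(midConvAfter),
              dropout = dropout, nClasses = as.integer(nClasses))
  class(cfg) <- "p3dConfig"
  cfg$shapes <- networkShapes(cfg)
  cfg
}

#' Desk-scale network configuration
#'
#' A reduced configuration (2 x 24 x 16 x 16 input, three dense blocks, no
#' temporal trim needed) with the same stem kernels and growth rate as the
#' full-scale network; its shape algebra also ends at 1 x 1 x 1. Intended
#' for single-CPU training runs on the desk-scale simulated dataset.
#'
#' @return a \code{p3dConfig}.
#' @export
deskNetConfig <- function() {
  p3dConfig(inputShape = c(2L, 24L, 16L, 16L), nBlocks = 3L,
            midConvAfter = NA)
}

#' Per-stage output shapes of the network
#'
#' Pure stride/padding arithmetic from input to the fully connected layer;
#' fails naming the first stage whose extent becomes non-positive.
#'
#' @param config a \code{\link{p3dConfig}} (the \code{shapes} element is
#'   ignored).
#' @return data.frame with columns \code{stage, c, t, h, w}.
#' @export
networkShapes <- function(config) {
  s <- config$inputShape   # c, t, h, w
  trace <- list(data.frame(stage = "input", c = s[1], t = s[2], h = s[3], w = s[4]))
  chk <- function(s, stage) {
    if (any(s <= 0)) stop(sprintf("stage '%s' yields non-positive extent", stage))
    s
  }
  s <- chk(c(config$stemChannels[1], s[2],
             .convOutDim(s[3], 7L, 2L, 3L), .convOutDim(s[4], 7L, 2L, 3L)),
           "stem_spatial")
  trace <- c(trace, list(data.frame(stage = "stem_spatial", c = s[1], t = s[2],
                                    h = s[3], w = s[4])))
  s <- chk(c(config$stemChannels[2], .convOutDim(s[2], 9L, 3L, 4L), s[3], s[4]),
           "stem_temporal")
  trace <- c(trace, list(data.frame(stage = "stem_temporal", c = s[1], t = s[2],
                                    h = s[3], w = s[4])))
  for (b in seq_len(config$nBlocks)) {
    if (any(s[2:4] < 2)) stop(sprintf("stage 'block_%d' has non-poolable extent", b))
    s <- chk(c(s[1] + 2L * config$growthRate, s[2] %/% 2L, s[3] %/% 2L, s[4] %/% 2L),
             sprintf("block_%d", b))
    trace <- c(trace, list(data.frame(stage = sprintf("block_%d", b), c = s[1],
                                      t = s[2], h = s[3], w = s[4])))
    if (!is.na(config$midConvAfter) && b == config$midConvAfter) {
      s <- chk(c(s[1], s[2] - 2L, s[3], s[4]), "mid_conv")
      trace <- c(trace, list(data.frame(stage = "mid_conv", c = s[1], t = s[2],
                                        h = s[3], w = s[4])))
    }
  }
  do.call(rbind, trace)
}

.initBN <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
.initBNState <- function(c) list(rm = rep(0, c), rv = rep(1, c))

.initConvW <- function(cOut, cIn, k) {
  array(.truncNorm(cOut * cIn * prod(k)), c(cOut, cIn, k))
}

#' Initialise the parameters of one dense P3D block
#'
#' @param cIn input channel count.
#' @param k growth rate.
#' @return list with elements \code{params} (BN scale/shift and the two
#'   convolution kernels) and \code{state} (BN running moments).
#' @export
initDenseBlock <- function(cIn, k) {
  list(params = list(bnS = .initBN(cIn), WS = .initConvW(k, cIn, c(1L, 3L, 3L)),
                     bnT = .initBN(cIn + k), WT = .initConvW(k, cIn + k, c(3L, 1L, 1L))),
       state = list(bnS = .initBNState(cIn), bnT = .initBNState(cIn + k)))
}

# BN -> ReLU -> conv composite used inside dense blocks.
.convUnitFwd <- function(X, params, state, W, kernel, pad, train) {
  bn <- .bnFwd(X, c(params, state), train)
  rl <- .reluFwd(bn$Y)
  cv <- .convFwd(rl$Y, W, NULL, stride = c(1L, 1L, 1L), pad = pad)
  list(Y = cv$Y, state = bn$state,
       cache = list(bn = bn$cache, relu = rl$cache, conv = cv$cache))
}

.convUnitBwd <- function(cache, dY) {
  cv <- .convBwd(cache$conv, dY)
  dr <- .reluBwd(cache$relu, cv$dX)
  bn <- .bnBwd(cache$bn, dr)
  list(dX = bn$dX, dW = cv$dW, dgamma = bn$dgamma, dbeta = bn$dbeta)
}

#' Forward pass of a densely connected P3D block
#'
#' Applies the block mapping
#' \code{Max[ConvT(ConvS(x) (+) x) (+) (ConvS(x) (+) x)]} to a tensor
#' \code{[c, t, h, w, n]}; the output has \code{c + 2k} channels and halved
#' (floored) extents. Requires all extents to be at least 2 (poolable).
#'
#' @param x input tensor array \code{[c, t, h, w, n]}.
#' @param block a block as from \code{\link{initDenseBlock}}.
#' @param train use batch statistics (TRUE) or running statistics (FALSE).
#' @return output tensor array.
#' @export
denseP3dBlock <- function(x, block, train = FALSE) {
  .blockFwd(x, block$params, block$state, train)$Y
}

.blockFwd <- function(X, params, state, train) {
  d <- dim(X)
  if (any(d[2:4] < 2)) stop("non-poolable extent (< 2) in dense block")
  k <- dim(params$WS)[1]
  us <- .convUnitFwd(X, params$bnS, state$bnS, params$WS,
                     kernel = c(1L, 3L, 3L), pad = c(0L, 1L, 1L), train)
  cat1 <- .catChannels(us$Y, X)
  ut <- .convUnitFwd(cat1, params$bnT, state$bnT, params$WT,
                     kernel = c(3L, 1L, 1L), pad = c(1L, 0L, 0L), train)
  cat2 <- .catChannels(ut$Y, cat1)
  pl <- .poolFwd(cat2)
  list(Y = pl$Y,
       state = list(bnS = us$state, bnT = ut$state),
       cache = list(us = us$cache, ut = ut$cache, pool = pl$cache,
                    k = k, cIn = d[1]))
}

.blockBwd <- function(cache, dY) {
  dcat2 <- .poolBwd(cache$pool, dY)
  sp2 <- .splitChannels(dcat2, cache$k)
  ut <- .convUnitBwd(cache$ut, sp2$dA)
  dcat1 <- ut$dX + sp2$dB
  sp1 <- .splitChannels(dcat1, cache$k)
  us <- .convUnitBwd(cache$us, sp1$dA)
  dX <- us$dX + sp1$dB
  list(dX = dX,
       grads = list(bnS = list(gamma = us$dgamma, beta = us$dbeta),
                    WS = us$dW,
                    bnT = list(gamma = ut$dgamma, beta = ut$dbeta),
                    WT = ut$dW))
}

#' Build the densely connected P3D classifier
#'
#' Initialises all parameters: truncated-normal weights (mean 0, sd 0.05,
#' truncated at 2 sd) for every convolution and zeros for the fully
#' connected layer, as in the training protocol.
#'
#' @param config a \code{\link{p3dConfig}}.
#' @param seed RNG seed for the initialisation.
#' @return a \code{p3dModel} list (config, params, state).
#' @export
buildNetwork <- function(config, seed = 1L) {
  stopifnot(inherits(config, "p3dConfig"))
  set.seed(seed)
  s <- config$inputShape
  k <- config$growthRate
  params <- list(
    stemS = list(W = .initConvW(config$stemChannels[1], s[1], c(1L, 7L, 7L)),
                 b = rep(0, config$stemChannels[1])),
    stemT = list(W = .initConvW(config$stemChannels[2], config$stemChannels[1],
                                c(9L, 1L, 1L)),
                 b = rep(0, config$stemChannels[2])))
  state <- list(blocks = vector("list", config$nBlocks))
  blocks <- vector("list", config$nBlocks)
  c <- config$stemChannels[2]
  for (b in seq_len(config$nBlocks)) {
    blk <- initDenseBlock(c, k)
    blocks[[b]] <- blk$params
    state$blocks[[b]] <- blk$state
    c <- c + 2L * k
    if (!is.na(config$midConvAfter) && b == config$midConvAfter) {
      params$mid <- list(W = .initConvW(c, c, c(3L, 1L, 1L)), b = rep(0, c))
    }
  }
  params$blocks <- blocks
  last <- config$shapes[nrow(config$shapes), ]
  flat <- last$c * last$t * last$h * last$w
  params$fc <- list(W = matrix(0, config$nClasses, flat),
                    b = rep(0, config$nClasses))
  model <- list(config = config, params = params, state = state, seed = seed)
  class(model) <- "p3dModel"
  model
}

#' @export
print.p3dModel <- function(x, ...) {
  np <- 0
  countLeaves <- function(a) {
    if (is.list(a)) for (e in a) countLeaves(e) else np <<- np + length(a)
  }
  countLeaves(x$params)
  cat(sprintf("Densely connected P3D classifier: %d dense blocks, k = %d, %d parameters\n",
              x$config$nBlocks, x$config$growthRate, np))
  print(x$config$shapes, row.names = FALSE)
  invisible(x)
}

# Full forward pass; X is [c, t, h, w, n]. Returns probabilities, logits,
# updated BN state, and (when keepCache) everything backward needs.
.netFwd <- function(model, X, train = FALSE, keepCache = FALSE) {
  p <- model$params; st <- model$state; cfg <- model$config
  cache <- list()
  c1 <- .convFwd(X, p$stemS$W, p$stemS$b, stride = c(1L, 2L, 2L), pad = c(0L, 3L, 3L))
  c2 <- .convFwd(c1$Y, p$stemT$W, p$stemT$b, stride = c(3L, 1L, 1L), pad = c(4L, 0L, 0L))
  cache$stemS <- c1$cache; cache$stemT <- c2$cache
  H <- c2$Y
  cache$blocks <- vector("list", cfg$nBlocks)
  for (b in seq_len(cfg$nBlocks)) {
    bf <- .blockFwd(H, p$blocks[[b]], st$blocks[[b]], train)
    st$blocks[[b]] <- bf$state
    cache$blocks[[b]] <- bf$cache
    H <- bf$Y
    if (!is.na(cfg$midConvAfter) && b == cfg$midConvAfter) {
      cm <- .convFwd(H, p$mid$W, p$mid$b, stride = c(1L, 1L, 1L), pad = c(0L, 0L, 0L))
      cache$mid <- cm$cache
      H <- cm$Y
    }
  }
  dp <- .dropoutFwd(H, cfg$dropout, train)
  cache$dropout <- dp$cache
  fc <- .fcFwd(dp$Y, p$fc$W, p$fc$b)
  cache$fc <- fc$cache
  sm <- .softmaxCE(fc$Y)
  list(probs = sm$P, logits = fc$Y, state = st,
       cache = if (keepCache) cache else NULL)
}

# Backward pass from dlogits; returns gradients shaped like model$params.
.netBwd <- function(model, cache, dlogits) {
  cfg <- model$config
  fc <- .fcBwd(cache$fc, dlogits)
  dH <- .dropoutBwd(cache$dropout, fc$dX)
  grads <- list(fc = list(W = fc$dW, b = fc$db))
  gblocks <- vector("list", cfg$nBlocks)
  for (b in rev(seq_len(cfg$nBlocks))) {
    if (!is.na(cfg$midConvAfter) && b == cfg$midConvAfter) {
      cm <- .convBwd(cache$mid, dH)
      grads$mid <- list(W = cm$dW, b = cm$db)
      dH <- cm$dX
    }
    bb <- .blockBwd(cache$blocks[[b]], dH)
    gblocks[[b]] <- bb$grads
    dH <- bb$dX
  }
  grads$blocks <- gblocks
  c2 <- .convBwd(cache$stemT, dH)
  grads$stemT <- list(W = c2$dW, b = c2$db)
  c1 <- .convBwd(cache$stemS, c2$dX)
  grads$stemS <- list(W = c1$dW, b = c1$db)
  grads
}
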
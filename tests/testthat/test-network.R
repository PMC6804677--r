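# Densely connected P3D classifier: shape algebra, block semantics,
# gradients, training behaviour and decision-threshold tuning.

test_that("the full-scale shape trace follows the stride arithmetic", {
  cfg <- p3dConfig()
  tr <- cfg$shapes
  get <- function(stage) unlist(tr[tr$stage == stage, c("c", "t", "h", "w")])
  expect_equal(unname(get("stem_spatial")), c(16, 120, 32, 32))
  expect_equal(unname(get("stem_temporal")), c(16, 40, 32, 32))
  expect_equal(unname(get("block_2")), c(48, 10, 8, 8))
  expect_equal(unname(get("mid_conv")), c(48, 8, 8, 8))
  expect_equal(unname(get("block_5")), c(96, 1, 1, 1))
})

test_that("invalid configurations fail naming the offending stage", {
  expect_error(p3dConfig(inputShape = c(2, 120, 2, 2)), "block_1|stem")
  expect_error(p3dConfig(inputShape = c(2, 6, 64, 64), nBlocks = 5),
               "block_")
})

test_that("dense blocks add exactly 2k channels and halve extents", {
  set.seed(1)
  for (trial in 1:4) {
    cIn <- sample(3:12, 1)
    k <- sample(2:6, 1)
    d <- c(cIn, 2 * sample(2:4, 1), 2 * sample(2:4, 1), 2 * sample(2:4, 1), 2)
    blk <- initDenseBlock(cIn, k)
    x <- array(rnorm(prod(d)), d)
    y <- denseP3dBlock(x, blk, train = TRUE)
    expect_identical(dim(y), as.integer(c(cIn + 2L * k, d[2] %/% 2L,
                                          d[3] %/% 2L, d[4] %/% 2L, d[5])))
  }
  blk <- initDenseBlock(4, 2)
  x <- array(rnorm(4 * 1 * 4 * 4), c(4, 1, 4, 4, 1))
  expect_error(denseP3dBlock(x, blk), "poolable")
})

test_that("a zero-weight block reduces to pooled concatenation with zeros", {
  # hand-checkable case: zero conv kernels and identity batch norm mean the
  # two conv outputs are zero channels; the block output must equal
  # max-pooled [0_k ; 0_k ; x]
  cIn <- 1L; k <- 1L
  blk <- initDenseBlock(cIn, k)
  blk$params$WS[] <- 0
  blk$params$WT[] <- 0
  x <- array(seq_len(1 * 4 * 4 * 4), c(1, 4, 4, 4, 1))
  y <- denseP3dBlock(x, blk, train = FALSE)  # running stats: identity BN
  expect_identical(dim(y), c(3L, 2L, 2L, 2L, 1L))
  expect_true(all(y[1, , , , ] == 0))
  expect_true(all(y[2, , , , ] == 0))
  # channel 3 = 2x2x2 max pool of x, verified against a hand computation
  xb <- x[1, , , , 1]
  hand <- array(0, c(2, 2, 2))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2)
    hand[a, b, cc] <- max(xb[2 * a - 1:0, 2 * b - 1:0, 2 * cc - 1:0])
  expect_equal(y[3, , , , 1], hand)
})

test_that("forward pass yields normalised class probabilities and batches", {
  cfg <- deskNetConfig()
  model <- buildNetwork(cfg, seed = 2)
  x <- array(rnorm(2 * 24 * 16 * 16 * 3), c(2, 24, 16, 16, 3))
  p <- predictProbabilities(model, x)
  expect_identical(dim(p), c(3L, 2L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- p3dConfig(inputShape = c(2L, 8L, 8L, 8L), growthRate = 2L,
                   stemChannels = c(3L, 3L), nBlocks = 1L,
                   midConvAfter = NA, dropout = 0)
  model <- buildNetwork(cfg, seed = 4)
  # non-trivial weights everywhere (FC initialises to zero by design)
  set.seed(5)
  model$params$fc$W[] <- rnorm(length(model$params$fc$W), 0, 0.3)
  x <- array(rnorm(2 * 8 * 8 * 8 * 3), c(2, 8, 8, 8, 3))
  y <- c(1L, 2L, 1L)
  lossAt <- function(m) {
    fw <- .netFwd(m, x, train = TRUE, keepCache = FALSE)
    .softmaxCE(fw$logits, y)$loss
  }
  fw <- .netFwd(model, x, train = TRUE, keepCache = TRUE)
  sm <- .softmaxCE(fw$logits, y)
  grads <- .netBwd(model, fw$cache, sm$dZ)
  paths <- list(c("stemS", "W"), c("stemT", "b"),
                list("blocks", 1L, "WS"), list("blocks", 1L, "WT"),
                list("blocks", 1L, "bnS", "gamma"),
                list("blocks", 1L, "bnT", "beta"), c("fc", "W"))
  h <- 1e-5
  set.seed(6)
  for (path in paths) {
    g <- grads; p <- model$params
    for (key in path) { g <- g[[key]]; p <- p[[key]] }
    for (rep in 1:3) {
      i <- sample(length(p), 1)
      mp <- model; mm <- model
      pp <- p; pp[i] <- pp[i] + h
      pm <- p; pm[i] <- pm[i] - h
      assignPath <- function(m, path, val) {
        expr <- "m$params"
        for (key in path) expr <- sprintf("%s[[%s]]",
          expr, if (is.character(key)) sprintf("'%s'", key) else key)
        eval(parse(text = sprintf("%s <- val", expr)))
        m
      }
      mp <- assignPath(mp, path, pp)
      mm <- assignPath(mm, path, pm)
      num <- (lossAt(mp) - lossAt(mm)) / (2 * h)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic and can overfit a tiny set", {
  toy <- toyVideoSet(n = 10)
  cfg <- p3dConfig(inputShape = c(2L, 24L, 16L, 16L), growthRate = 4L,
                   stemChannels = c(6L, 6L), nBlocks = 3L, midConvAfter = NA,
                   dropout = 0)
  tc <- trainConfig(learningRate = 2e-3, batchSize = 10, epochs = 40,
                    augment = FALSE, seed = 7)
  m1 <- trainNetwork(buildNetwork(cfg, seed = 7), toy$x, toy$y, config = tc)
  m2 <- trainNetwork(buildNetwork(cfg, seed = 7), toy$x, toy$y,
                     config = trainConfig(learningRate = 2e-3, batchSize = 10,
                                          epochs = 1, augment = FALSE, seed = 7))
  expect_identical(m1$metrics$loss[1], m2$metrics$loss[1])
  p <- predictProbabilities(m1, toy$x)[, 2]
  expect_identical(as.integer(p >= 0.5), toy$y)   # 100% training accuracy
})

test_that("degenerate training inputs are rejected", {
  toy <- toyVideoSet(n = 6)
  cfg <- p3dConfig(inputShape = c(2L, 24L, 16L, 16L), growthRate = 2L,
                   stemChannels = c(4L, 4L), nBlocks = 3L, midConvAfter = NA)
  m <- buildNetwork(cfg)
  expect_error(trainNetwork(m, toy$x, rep(1L, 6)), "each class")
})

test_that("threshold tuning finds the smallest zero-FP grid point plus safety", {
  s1 <- c(0.1, 0.2, 0.4, 0.6, 0.8, 0.95)
  y1 <- c(0, 0, 0, 1, 1, 1)
  th <- tuneDecisionThreshold(s1, y1)
  expect_equal(th$base, 0.5)
  expect_equal(th$value, 0.9)
  # a negative at 0.995 forces 0.999, safety 0.9999 (exhaustive scan oracle)
  s2 <- c(0.3, 0.995, 0.9, 0.999, 1, 1)
  y2 <- c(0, 0, 0, 1, 1, 1)
  grid <- c(0.5, 1 - 10^-(1:15))
  oracle <- grid[min(which(vapply(grid, function(t) all(s2[y2 == 0] < t),
                                  logical(1))))]
  th2 <- tuneDecisionThreshold(s2, y2)
  expect_equal(th2$base, oracle)
  expect_equal(th2$base, 0.999)
  expect_equal(th2$value, 0.9999)
  expect_error(tuneDecisionThreshold(c(1, 0.9), c(0, 1)), "no valid")
  expect_error(tuneDecisionThreshold(c(0.2, 0.9), c(1, 1)), "negative")
})

test_that("raising the threshold never increases the positive count", {
  set.seed(8)
  s <- runif(200)
  grid <- c(0.5, 1 - 10^-(1:8))
  counts <- vapply(grid, function(t) sum(s >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("classification respects the threshold boundary convention", {
  toy <- toyVideoSet(n = 4)
  cfg <- p3dConfig(inputShape = c(2L, 24L, 16L, 16L), growthRate = 2L,
                   stemChannels = c(4L, 4L), nBlocks = 3L, midConvAfter = NA)
  m <- buildNetwork(cfg, seed = 1)
  out <- classifyVideos(m, toy$x, threshold = 0.5)
  expect_identical(out$positive, out$probability >= 0.5)
  # the operating threshold rejects a 0.9999 score
  expect_false(0.9999 >= 0.999999)
  empty <- classifyVideos(m, list(), threshold = 0.5)
  expect_identical(nrow(empty), 0L)
})
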
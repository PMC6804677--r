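# Training protocol for the video classifier: Adam on cross-entropy with
# mirror/rotation augmentation, per-epoch validation metrics, and the
# zero-false-positive decision-threshold tuning procedure.

#' Training configuration
#'
#' The full-scale protocol mirrors the acquisition-scale setup (Adam,
#' learning rate 1e-4, batch size 240, 800 epochs, mirror + 90/180/270
#' degree rotation augmentation); \code{deskTrainConfig} is the named
#' single-CPU profile used with \code{\link{deskNetConfig}}.
#'
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param epochs number of epochs.
#' @param augment random per-video mirroring and rotation (90/180/270).
#' @param seed RNG seed controlling shuffling, augmentation and dropout.
#' @return a \code{trainConfig} list.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 240L, epochs = 800L,
                        augment = TRUE, seed = 1L) {
  stopifnot(learningRate > 0, batchSize >= 1)
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), augment = augment,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' @rdname trainConfig
#' @export
deskTrainConfig <- function(learningRate = 1e-3, batchSize = 40L, epochs = 60L,
                            augment = TRUE, seed = 1L) {
  trainConfig(learningRate, batchSize, epochs, augment, seed)
}

# Rotate the spatial dims of [c, t, h, w] by quarter turns; mirror flips w.
.augmentVideo <- function(v, mirror, quarter) {
  if (mirror) v <- v[, , , rev(seq_len(dim(v)[4])), drop = FALSE]
  if (quarter %% 4 != 0) {
    for (q in seq_len(quarter %% 4)) {
      v <- aperm(v, c(1, 2, 4, 3))                 # transpose h/w
      v <- v[, , rev(seq_len(dim(v)[3])), , drop = FALSE]  # flip rows
    }
  }
  v
}

# Coerce input videos (list of CandidateVideo, list of arrays, or a
# [c, t, h, w, n] array) to the batch tensor layout.
.asBatchTensor <- function(x) {
  if (is.array(x) && length(dim(x)) == 5L) return(x)
  if (is.array(x) && length(dim(x)) == 4L) {
    dim(x) <- c(dim(x), 1L)
    return(x)
  }
  stopifnot(is.list(x), length(x) >= 1)
  first <- x[[1]]
  getv <- function(e) if (is(e, "CandidateVideo")) e@values else e
  d <- dim(getv(first))
  out <- array(0, c(d, length(x)))
  for (i in seq_along(x)) out[, , , , i] <- getv(x[[i]])
  out
}

.asBinaryLabels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two classes")
    return(as.integer(labels) - 1L)  # second level = positive
  }
  l <- as.integer(labels)
  if (!all(l %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  l
}

.adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  opt$m <- .mapLeaves(function(m, g, ...) beta1 * m + (1 - beta1) * g,
                      opt$m, grads)
  opt$v <- .mapLeaves(function(v, g, ...) beta2 * v + (1 - beta2) * g^2,
                      opt$v, grads)
  params <- .mapLeaves(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                       params, opt$m, opt$v)
  list(params = params, opt = opt)
}

#' Train the video classifier
#'
#' Optimises the softmax cross-entropy with Adam under random per-video
#' mirroring/rotation augmentation, logging loss and (when a validation set
#' is supplied) validation sensitivity and specificity at probability
#' threshold 0.5 for every epoch. Fully deterministic for a fixed
#' \code{config$seed}.
#'
#' @param model a \code{\link{buildNetwork}} model.
#' @param x training videos: list of \linkS4class{CandidateVideo} (or
#'   arrays), or a \code{[c, t, h, w, n]} array.
#' @param labels binary labels (logical, 0/1, or a two-level factor whose
#'   second level is the positive class); both classes must be present with
#'   at least two examples each.
#' @param valX,valLabels optional validation set (never augmented).
#' @param config a \code{\link{trainConfig}}.
#' @param verbose print one line per epoch.
#' @return the trained model, with a \code{metrics} data.frame
#'   (epoch, loss, valSensitivity, valSpecificity) attached.
#' @export
trainNetwork <- function(model, x, labels, valX = NULL, valLabels = NULL,
                         config = trainConfig(), verbose = FALSE) {
  stopifnot(inherits(model, "p3dModel"))
  X <- .asBatchTensor(x)
  y <- .asBinaryLabels(labels)
  n <- dim(X)[5]
  stopifnot(length(y) == n)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("training data must contain at least two examples of each class")
  haveVal <- !is.null(valX)
  if (haveVal) {
    Xv <- .asBatchTensor(valX)
    yv <- .asBinaryLabels(valLabels)
  }
  set.seed(config$seed)
  opt <- list(t = 0L,
              m = .mapLeaves(function(p, ...) p * 0, model$params),
              v = .mapLeaves(function(p, ...) p * 0, model$params))
  metrics <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batchSize)) {
      idx <- perm[start:min(start + config$batchSize - 1L, n)]
      Xb <- X[, , , , idx, drop = FALSE]
      if (config$augment) {
        for (j in seq_along(idx)) {
          Xb[, , , , j] <- .augmentVideo(Xb[, , , , j, drop = FALSE][, , , , 1],
                                         mirror = stats::runif(1) < 0.5,
                                         quarter = sample(0:3, 1))
        }
      }
      fw <- .netFwd(model, Xb, train = TRUE, keepCache = TRUE)
      model$state <- fw$state
      sm <- .softmaxCE(fw$logits, y[idx] + 1L)
      losses <- c(losses, sm$loss)
      grads <- .netBwd(model, fw$cache, sm$dZ)
      up <- .adamStep(model$params, grads, opt, config$learningRate)
      model$params <- up$params
      opt <- up$opt
    }
    sens <- spec <- NA_real_
    if (haveVal) {
      pv <- predictProbabilities(model, Xv)[, 2]
      sens <- mean(pv[yv == 1] >= 0.5)
      spec <- mean(pv[yv == 0] < 0.5)
    }
    metrics[[ep]] <- data.frame(epoch = ep, loss = mean(losses),
                                valSensitivity = sens, valSpecificity = spec)
    if (verbose)
      message(sprintf("epoch %3d | loss %.4f | val sens %.3f spec %.3f",
                      ep, mean(losses), sens, spec))
  }
  model$metrics <- do.call(rbind, metrics)
  model$trainConfig <- config
  model
}

#' Class probabilities for a set of videos
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no
#' dropout). Softmax outputs sum to one per video.
#'
#' @param model a trained \code{p3dModel}.
#' @param x videos as in \code{\link{trainNetwork}}.
#' @param batchSize evaluation batch size.
#' @return matrix n x 2 with columns \code{negative}, \code{positive}.
#' @export
predictProbabilities <- function(model, x, batchSize = 64L) {
  X <- .asBatchTensor(x)
  n <- dim(X)[5]
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("negative", "positive")))
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    fw <- .netFwd(model, X[, , , , idx, drop = FALSE], train = FALSE)
    out[idx, ] <- t(fw$probs)
  }
  out
}

#' Tune the decision threshold to zero false positives
#'
#' Scans the threshold grid 0.5, 0.9, 0.99, 0.999, ... and returns the
#' smallest threshold with zero false positives on the pooled score set,
#' then applies a safety step of one more decade toward 1 (0.99999 becomes
#' 0.999999) to guard against overfitting of the scores themselves.
#'
#' @param scores positive-class probabilities in [0, 1].
#' @param labels binary labels matching \code{scores}.
#' @param safetyExponent number of extra grid decades applied (default 1).
#' @return a \code{DecisionThreshold} list: \code{value} (in [0.5, 1)),
#'   \code{base} (pre-safety threshold), \code{safetyApplied}.
#' @export
tuneDecisionThreshold <- function(scores, labels, safetyExponent = 1L) {
  y <- .asBinaryLabels(labels)
  stopifnot(length(scores) == length(y), all(scores >= 0 & scores <= 1))
  if (!any(y == 0)) stop("at least one negative example is required")
  neg <- scores[y == 0]
  if (any(neg >= 1)) stop("a negative example has score 1.0: no valid threshold")
  grid <- c(0.5, 1 - 10^-(1:15))
  ok <- which(vapply(grid, function(th) all(neg < th), logical(1)))
  if (!length(ok)) stop("no grid threshold eliminates all false positives")
  i <- ok[1]
  j <- min(i + safetyExponent, length(grid))
  structure(list(value = grid[j], base = grid[i],
                 safetyApplied = safetyExponent > 0),
            class = "DecisionThreshold")
}

#' Classify candidate videos at a decision threshold
#'
#' A video is called positive iff its positive-class probability is greater
#' than or equal to the threshold value.
#'
#' @param model a trained \code{p3dModel}.
#' @param x videos (possibly an empty list).
#' @param threshold a \code{DecisionThreshold} from
#'   \code{\link{tuneDecisionThreshold}}, or a plain probability.
#' @return data.frame with columns \code{probability}, \code{positive}.
#' @export
classifyVideos <- function(model, x, threshold) {
  th <- if (inherits(threshold, "DecisionThreshold")) threshold$value else threshold
  if (is.list(x) && length(x) == 0)
    return(data.frame(probability = numeric(0), positive = logical(0)))
  p <- predictProbabilities(model, x)[, 2]
  data.frame(probability = p, positive = p >= th)
}
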
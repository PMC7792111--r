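#' @include AllClasses.R AllGenerics.R utils.R constructors.R
NULL

#' Build a small trainable convolutional network
#'
#' A desk-scale differentiable classifier: a 2x2 average-pooling stem,
#' two 3x3 convolution + ReLU + 2x2 max-pool blocks, and a final fully
#' connected layer with `nClasses` outputs. It satisfies the full
#' [Classifier-class] contract, including exact input-pixel gradients of
#' the cross-entropy loss (the quantity FGSM needs). Weights are
#' He-initialized from the given seed; two builds with the same seed are
#' identical.
#'
#' @param inputShape integer `(H, W, C)`; `H` and `W` must be multiples
#'   of 8 (three halvings of spatial resolution).
#' @param nClasses number of classes (>= 2).
#' @param seed integer seed for weight initialization.
#' @param filters numbers of filters in the two conv blocks.
#' @return a `SmallCNN` classifier.
#' @examples
#' net <- buildSmallCnn(c(16, 16, 1), nClasses = 3, seed = 1)
#' @export
buildSmallCnn <- function(inputShape, nClasses, seed = 1L,
                          filters = c(8L, 16L)) {
  inputShape <- as.integer(inputShape)
  if (length(inputShape) != 3L || any(inputShape < 1L))
    stop("inputShape must be a positive (H, W, C) triple")
  if (nClasses < 2L) stop("nClasses must be >= 2")
  h <- inputShape[1]; w <- inputShape[2]; ch <- inputShape[3]
  if (h %% 8L != 0L || w %% 8L != 0L)
    stop("image height and width must be multiples of 8")
  if (!ch %in% c(1L, 3L)) stop("channels must be 1 or 3")
  f1 <- as.integer(filters[1]); f2 <- as.integer(filters[2])
  dfc <- (h %/% 8L) * (w %/% 8L) * f2
  params <- withSeed(seed, list(
    W1 = matrix(stats::rnorm(f1 * 9 * ch, sd = sqrt(2 / (9 * ch))),
                f1, 9 * ch),
    b1 = numeric(f1),
    W2 = matrix(stats::rnorm(f2 * 9 * f1, sd = sqrt(2 / (9 * f1))),
                f2, 9 * f1),
    b2 = numeric(f2),
    Wf = matrix(stats::rnorm(nClasses * dfc, sd = sqrt(1 / dfc)),
                nClasses, dfc),
    bf = numeric(nClasses)))
  new("SmallCNN", params = params, shape = inputShape,
      k = as.integer(nClasses), id = sprintf("smallcnn-seed%d", seed),
      trained = FALSE)
}

checkInputShape <- function(object, arr) {
  if (!identical(as.integer(dim(arr)[2:4]), object@shape))
    stop("image shape (", paste(dim(arr)[2:4], collapse = "x"),
         ") does not match the classifier input shape (",
         paste(object@shape, collapse = "x"), ")")
}

#' @rdname classScores
#' @export
setMethod("classScores", "SmallCNN", function(object, x) {
  arr <- asImageArray(x)
  checkInputShape(object, arr)
  s <- object@shape
  t(cpp_cnn_scores(object@params, flattenBatch(arr), s[1], s[2], s[3]))
})

#' @rdname classScores
#' @export
setMethod("classScores", "FunctionClassifier", function(object, x) {
  arr <- asImageArray(x)
  sc <- object@scoreFun(arr)
  if (!is.matrix(sc) || nrow(sc) != dim(arr)[1] || ncol(sc) != object@k)
    stop("scoreFun must return an N x K matrix")
  sc
})

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "Classifier", function(object, x) {
  max.col(classScores(object, x), ties.method = "first")
})

#' @rdname lossGradient
#' @export
setMethod("lossGradient", "SmallCNN", function(object, x, labels) {
  arr <- asImageArray(x)
  checkInputShape(object, arr)
  labels <- as.integer(labels)
  if (length(labels) != dim(arr)[1])
    stop("need one label per image")
  if (any(labels < 1L | labels > object@k)) stop("label out of range")
  s <- object@shape
  g <- cpp_cnn_grads(object@params, flattenBatch(arr), labels - 1L,
                     s[1], s[2], s[3], FALSE, TRUE, FALSE)
  unflattenBatch(g$gx, s)
})

#' @rdname lossGradient
#' @export
setMethod("lossGradient", "FunctionClassifier", function(object, x, labels) {
  if (is.null(object@gradFun))
    stop("this external classifier supplies no gradient function")
  arr <- asImageArray(x)
  g <- object@gradFun(arr, as.integer(labels))
  if (!identical(dim(g), dim(arr)))
    stop("gradFun must return an array with the batch's shape")
  g
})

#' Learning rate for a given epoch
#'
#' Piecewise-constant schedule lookup: the rate of the first schedule
#' row whose `untilEpoch` is `>= epoch`. With the default schedule:
#' 0.001 through epoch 40, 1e-4 for epochs 41-45, 1e-5 beyond.
#'
#' @param config a [trainConfig()].
#' @param epoch epoch number (>= 1).
#' @return the learning rate.
#' @export
learningRateAt <- function(config, epoch) {
  stopifnot(epoch >= 1)
  s <- config@lrSchedule[order(config@lrSchedule$untilEpoch), ]
  s$lr[match(TRUE, epoch <= s$untilEpoch,
             nomatch = nrow(s))]
}

# nearest-neighbour rotation + shift of one (H,W,C) image; border fill is
# the nearest valid pixel
augmentOne <- function(img, angleDeg, shiftY, shiftX, grid) {
  th <- angleDeg * pi / 180
  sy <- grid$u * cos(th) - grid$v * sin(th) + grid$cy - shiftY
  sx <- grid$u * sin(th) + grid$v * cos(th) + grid$cx - shiftX
  si <- pmin(pmax(round(sy), 1L), grid$h)
  sj <- pmin(pmax(round(sx), 1L), grid$w)
  out <- img
  for (ch in seq_len(dim(img)[3]))
    out[, , ch] <- matrix(img[, , ch][cbind(si, sj)], grid$h, grid$w)
  out
}

augmentGrid <- function(h, w) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  list(u = as.vector(yy - cy), v = as.vector(xx - cx),
       cy = cy, cx = cx, h = h, w = w)
}

# per-epoch index vector with minority classes resampled (with
# replacement) to the majority count
oversampleIndices <- function(labels, k) {
  counts <- tabulate(labels, nbins = k)
  target <- max(counts)
  unlist(lapply(seq_len(k), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == target) idx
    else c(idx, sample(idx, target - length(idx), replace = TRUE))
  }), use.names = FALSE)
}

#' @rdname trainClassifier
#' @export
setMethod("trainClassifier", "SmallCNN", function(object, trainSet, config) {
  stopifnot(is(trainSet, "ImageSet"), is(config, "TrainConfig"))
  arr <- images(trainSet)
  checkInputShape(object, arr)
  lab <- labels(trainSet)
  if (length(unique(lab)) < object@k)
    stop("training labels must cover every class")
  s <- object@shape
  params <- object@params
  vel <- lapply(params, function(p) p * 0)
  grid <- augmentGrid(s[1], s[2])
  doAug <- config@augmentRotationDeg > 0 || config@augmentShiftFrac > 0
  log <- data.frame(epoch = seq_len(config@epochs), lr = NA_real_,
                    trainLoss = NA_real_)
  withSeed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      idx <- if (config@oversample) oversampleIndices(lab, object@k)
             else seq_along(lab)
      idx <- sample(idx)
      lr <- learningRateAt(config, epoch)
      epochArr <- arr[idx, , , , drop = FALSE]
      if (doAug) {
        for (i in seq_len(dim(epochArr)[1])) {
          a <- stats::runif(1, -config@augmentRotationDeg,
                            config@augmentRotationDeg)
          dy <- stats::runif(1, -config@augmentShiftFrac,
                             config@augmentShiftFrac) * s[1]
          dx <- stats::runif(1, -config@augmentShiftFrac,
                             config@augmentShiftFrac) * s[2]
          img <- epochArr[i, , , , drop = FALSE]
          dim(img) <- dim(epochArr)[2:4]
          epochArr[i, , , ] <- augmentOne(img, a, dy, dx, grid)
        }
      }
      xmat <- flattenBatch(epochArr)
      y <- lab[idx]
      epochLoss <- 0
      starts <- seq(1L, length(y), by = config@batchSize)
      for (b in starts) {
        sel <- b:min(b + config@batchSize - 1L, length(y))
        g <- cpp_cnn_grads(params, xmat[, sel, drop = FALSE],
                           y[sel] - 1L, s[1], s[2], s[3],
                           TRUE, FALSE, TRUE)
        gl <- list(W1 = g$gW1, b1 = as.numeric(g$gb1),
                   W2 = g$gW2, b2 = as.numeric(g$gb2),
                   Wf = g$gWf, bf = as.numeric(g$gbf))
        for (nm in names(params)) {
          vel[[nm]] <- config@momentum * vel[[nm]] - lr * gl[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        epochLoss <- epochLoss + g$loss * length(sel)
      }
      log$lr[epoch] <- lr
      log$trainLoss[epoch] <- epochLoss / length(y)
    }
  })
  object@params <- params
  object@trained <- TRUE
  attr(object, "trainingLog") <- log
  object
})

#' Per-epoch training log of a trained small CNN
#'
#' @param object a classifier returned by [trainClassifier()].
#' @return a data.frame with columns `epoch`, `lr`, `trainLoss`, or
#'   `NULL` for models without a recorded log.
#' @export
trainingLog <- function(object) attr(object, "trainingLog")

#' Classification accuracy on a dataset
#'
#' Fraction of images whose predicted label equals the true label.
#'
#' @param handle a classifier.
#' @param dataset an [ImageSet-class].
#' @return a fraction in `[0, 1]`.
#' @export
accuracy <- function(handle, dataset) {
  stopifnot(nImages(dataset) > 0)
  mean(predictLabels(handle, dataset) == labels(dataset))
}
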
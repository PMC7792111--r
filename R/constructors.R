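#' @include AllClasses.R AllGenerics.R
NULL

#' Create a synthetic task specification
#'
#' @param nClasses number of classes.
#' @param classProportions positive class weights (default balanced).
#' @param imageHeight,imageWidth image size in pixels.
#' @param channels 1 or 3.
#' @param patternFamily `"blob"`, `"stripe"` or `"texture"`.
#' @param noiseSd pixel-noise standard deviation (difficulty knob).
#' @param nTrain,nTest split sizes.
#' @param classNames optional class names.
#' @param seed integer seed.
#' @return a [SyntheticTaskSpec-class].
#' @examples
#' spec <- syntheticTaskSpec(nClasses = 4, nTrain = 40, nTest = 12,
#'                           imageHeight = 16, imageWidth = 16)
#' @export
syntheticTaskSpec <- function(nClasses = 4L,
                              classProportions = rep(1, nClasses),
                              imageHeight = 64L, imageWidth = 64L,
                              channels = 1L, patternFamily = "blob",
                              noiseSd = 0.1, nTrain = 2000L, nTest = 400L,
                              classNames = character(0), seed = 1L) {
  new("SyntheticTaskSpec", nClasses = as.integer(nClasses),
      classProportions = as.numeric(classProportions),
      imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth), channels = as.integer(channels),
      patternFamily = patternFamily, noiseSd = noiseSd,
      nTrain = as.integer(nTrain), nTest = as.integer(nTest),
      classNames = classNames, seed = as.integer(seed))
}

#' Create an ImageSet
#'
#' @param images numeric array `(N, H, W, C)` with pixels in `[0, 1]`.
#' @param labels integer labels `1..K`.
#' @param classNames character vector of length `K`.
#' @param split `"train"` or `"test"`.
#' @return an [ImageSet-class].
#' @export
imageSet <- function(images, labels, classNames, split = "train") {
  new("ImageSet", images = images, labels = as.integer(labels),
      classNames = classNames, split = split)
}

#' Create a perturbation budget
#'
#' Converts the relative budget `zeta` (percent) into the absolute
#' radius `xi = zeta/100 * referenceNorm`, where the reference is the
#' average image L_p norm of a dataset (computed here when `dataset` is
#' supplied, else passed directly as `referenceNorm`).
#'
#' @param p norm order, `2` or `Inf`.
#' @param zeta relative budget in percent.
#' @param dataset optional [ImageSet-class] used to compute the
#'   reference norm.
#' @param referenceNorm the average image norm (ignored when `dataset`
#'   is given).
#' @return a [PerturbationBudget-class].
#' @examples
#' b <- perturbationBudget(p = 2, zeta = 8, referenceNorm = 30)
#' b@xi  # 2.4
#' @export
perturbationBudget <- function(p = 2, zeta, dataset = NULL,
                               referenceNorm = NULL) {
  if (!is.null(dataset)) referenceNorm <- averageImageNorm(dataset, p)
  if (is.null(referenceNorm))
    stop("supply either a dataset or a referenceNorm")
  new("PerturbationBudget", p = as.numeric(p), zeta = as.numeric(zeta),
      xi = as.numeric(zeta) / 100 * as.numeric(referenceNorm),
      referenceNorm = as.numeric(referenceNorm))
}

#' Create an attack configuration
#'
#' Defaults follow the reference attack setting: FGSM step `epsilon`
#' interpreted in the canonical `[0, 1]` pixel domain, and `iMax = 15`
#' full passes over the image set.
#'
#' @param epsilon FGSM step size (> 0).
#' @param iMax maximum number of passes over the image set.
#' @param mode `"nontargeted"` or `"targeted"`.
#' @param targetClass target class index (`1..K`), targeted mode only.
#' @param seed integer seed for the per-pass visiting order.
#' @return an [AttackConfig-class].
#' @export
attackConfig <- function(epsilon = 0.002, iMax = 15L,
                         mode = c("nontargeted", "targeted"),
                         targetClass = NA_integer_, seed = 1L) {
  mode <- match.arg(mode)
  new("AttackConfig", epsilon = epsilon, iMax = as.integer(iMax),
      mode = mode, targetClass = as.integer(targetClass),
      seed = as.integer(seed))
}

#' Create a training configuration
#'
#' @param batchSize minibatch size.
#' @param epochs number of training epochs.
#' @param momentum SGD momentum.
#' @param lrSchedule data.frame with columns `untilEpoch` and `lr`; the
#'   default is the reference schedule (0.001 to epoch 40, 1e-4 to 45,
#'   1e-5 after).
#' @param augmentRotationDeg rotation augmentation range in degrees.
#' @param augmentShiftFrac shift augmentation range as a fraction of the
#'   image size.
#' @param oversample oversample minority classes each epoch.
#' @param seed integer seed.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(batchSize = 32L, epochs = 50L, momentum = 0.9,
                        lrSchedule = data.frame(
                          untilEpoch = c(40, 45, Inf),
                          lr = c(1e-3, 1e-4, 1e-5)),
                        augmentRotationDeg = 5, augmentShiftFrac = 0.05,
                        oversample = FALSE, seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), momentum = momentum,
      lrSchedule = lrSchedule, augmentRotationDeg = augmentRotationDeg,
      augmentShiftFrac = augmentShiftFrac, oversample = oversample,
      seed = as.integer(seed))
}

newUAP <- function(rho, budget, config, sourceModelId) {
  new("UAP", rho = rho, budget = budget, config = config,
      sourceModelId = sourceModelId,
      achievedNorm = lpNorm(rho, budget@p))
}

#' Wrap external score/gradient functions as a classifier
#'
#' Adapts any externally supplied model to the [Classifier-class]
#' contract. `scoreFun` must map an `(N, H, W, C)` batch to an `N x K`
#' score matrix; `gradFun`, if given, must map `(batch, labels)` to the
#' per-image input-loss gradient with the batch's shape (required only
#' by gradient-based attacks, not by evaluation).
#'
#' @param scoreFun batch score function.
#' @param inputShape integer `(H, W, C)`.
#' @param nClasses number of classes.
#' @param gradFun optional input-gradient function.
#' @param id model identifier string.
#' @return a `FunctionClassifier`.
#' @export
functionClassifier <- function(scoreFun, inputShape, nClasses,
                               gradFun = NULL, id = "external") {
  new("FunctionClassifier", scoreFun = scoreFun, gradFun = gradFun,
      shape = as.integer(inputShape), k = as.integer(nClasses), id = id)
}

#' Accessors for ImageSet
#'
#' @param x an [ImageSet-class].
#' @return `images()` the pixel array, `classNames()` the class names,
#'   `imageSplit()` the split role, `nImages()` the image count,
#'   `labels()` the integer labels.
#' @name ImageSet-accessors
NULL

#' @rdname ImageSet-accessors
#' @export
setMethod("images", "ImageSet", function(x) x@images)

#' @rdname ImageSet-accessors
#' @param object an [ImageSet-class] (for `labels`).
#' @param ... ignored.
#' @export
setMethod("labels", "ImageSet", function(object, ...) object@labels)

#' @rdname ImageSet-accessors
#' @export
setMethod("classNames", "ImageSet", function(x) x@classNames)

#' @rdname ImageSet-accessors
#' @export
setMethod("imageSplit", "ImageSet", function(x) x@split)

#' @rdname ImageSet-accessors
#' @export
setMethod("nImages", "ImageSet", function(x) dim(x@images)[1])

#' Dimensions of an ImageSet (`N`, `H`, `W`, `C`)
#' @param x an [ImageSet-class].
#' @export
setMethod("dim", "ImageSet", function(x) dim(x@images))

#' Subset an ImageSet by image index
#' @param x an [ImageSet-class].
#' @param i integer or logical index over images.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ImageSet", function(x, i, j, ..., drop = FALSE) {
  new("ImageSet", images = x@images[i, , , , drop = FALSE],
      labels = x@labels[i], classNames = x@classNames, split = x@split)
})

#' Classifier accessors
#'
#' @param object a classifier.
#' @return `nClasses()` the number of classes, `inputShape()` the
#'   `(H, W, C)` input shape, `modelId()` the identifier string.
#' @name classifier-accessors
NULL

#' @rdname classifier-accessors
#' @export
setMethod("nClasses", "SmallCNN", function(object) object@k)
#' @rdname classifier-accessors
#' @export
setMethod("inputShape", "SmallCNN", function(object) object@shape)
#' @rdname classifier-accessors
#' @export
setMethod("modelId", "SmallCNN", function(object) object@id)
#' @rdname classifier-accessors
#' @export
setMethod("nClasses", "FunctionClassifier", function(object) object@k)
#' @rdname classifier-accessors
#' @export
setMethod("inputShape", "FunctionClassifier", function(object) object@shape)
#' @rdname classifier-accessors
#' @export
setMethod("modelId", "FunctionClassifier", function(object) object@id)

setMethod("show", "ImageSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("ImageSet (%s): %d images, %dx%dx%d, %d classes\n",
              object@split, d[1], d[2], d[3], d[4],
              length(object@classNames)))
  tab <- table(factor(object@labels, levels = seq_along(object@classNames),
                      labels = object@classNames))
  print(tab)
})

setMethod("show", "PerturbationBudget", function(object) {
  cat(sprintf("PerturbationBudget: p=%s zeta=%g%% xi=%g (ref norm %g)\n",
              format(object@p), object@zeta, object@xi, object@referenceNorm))
})

setMethod("show", "UAP", function(object) {
  d <- dim(object@rho)
  cat(sprintf("UAP %dx%dx%d from '%s': ||rho||_%s = %g (budget xi = %g)\n",
              d[1], d[2], d[3], object@sourceModelId,
              format(object@budget@p), object@achievedNorm,
              object@budget@xi))
  if (!is.null(object@config))
    cat(sprintf("  mode=%s eps=%g iMax=%d seed=%d\n", object@config@mode,
                object@config@epsilon, object@config@iMax,
                object@config@seed))
})

setMethod("show", "SmallCNN", function(object) {
  cat(sprintf("SmallCNN '%s': input %s, %d classes, %s\n", object@id,
              paste(object@shape, collapse = "x"), object@k,
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s split, %d images, uap=%s]\n",
              object@split, object@nImages, object@uapId))
  cat(sprintf("  %s = %.4f", object@metric, object@value))
  if (!is.na(object@baseline))
    cat(sprintf(" (baseline %.4f, target class %d)", object@baseline,
                object@targetClass))
  cat("\n")
  if (length(object@dominantClasses))
    cat("  dominant classes:", paste(object@dominantClasses, collapse = ", "),
        "\n")
})
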
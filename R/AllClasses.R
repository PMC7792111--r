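setClassUnion("functionOrNULL", c("function", "NULL"))

#' Synthetic image-classification task description
#'
#' Describes a seeded synthetic task: how many classes, their relative
#' frequencies, image geometry, which pattern family carries the class
#' signal, and how much pixel noise is stacked on top. The pattern
#' families give each class a distinct, learnable structure: `blob`
#' places a Gaussian bright spot at a class-specific position, `stripe`
#' draws a sinusoidal grating with class-specific frequency and
#' orientation, and `texture` synthesizes band-pass filtered noise with a
#' class-specific spatial scale. `noiseSd` is the difficulty knob: i.i.d.
#' Gaussian pixel noise (canonical `[0, 1]` intensity units) added before
#' clipping.
#'
#' @slot nClasses number of classes (>= 2).
#' @slot classProportions positive weights, one per class; only ratios
#'   matter.
#' @slot imageHeight,imageWidth image size in pixels.
#' @slot channels 1 (grayscale) or 3 (RGB; classes additionally get a
#'   distinct color tint).
#' @slot patternFamily `"blob"`, `"stripe"` or `"texture"`.
#' @slot noiseSd pixel-noise standard deviation.
#' @slot nTrain,nTest split sizes (each >= `nClasses`).
#' @slot classNames optional class names; auto-generated when empty.
#' @slot seed integer seed; identical spec + seed reproduces identical
#'   arrays bitwise.
#' @seealso [generateDataset()]
#' @export
setClass("SyntheticTaskSpec",
  representation(nClasses = "integer", classProportions = "numeric",
                 imageHeight = "integer", imageWidth = "integer",
                 channels = "integer", patternFamily = "character",
                 noiseSd = "numeric", nTrain = "integer", nTest = "integer",
                 classNames = "character", seed = "integer"))

setValidity("SyntheticTaskSpec", function(object) {
  msg <- character(0)
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (length(object@classProportions) != object@nClasses)
    msg <- c(msg, "classProportions length must equal nClasses")
  if (any(object@classProportions <= 0))
    msg <- c(msg, "classProportions must all be > 0")
  if (object@imageHeight < 1L || object@imageWidth < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (!object@channels %in% c(1L, 3L)) msg <- c(msg, "channels must be 1 or 3")
  if (!object@patternFamily %in% c("blob", "stripe", "texture"))
    msg <- c(msg, "patternFamily must be blob, stripe or texture")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nTrain < object@nClasses || object@nTest < object@nClasses)
    msg <- c(msg, "nTrain and nTest must be >= nClasses")
  if (length(object@classNames) &&
      length(object@classNames) != object@nClasses)
    msg <- c(msg, "classNames length must equal nClasses")
  if (length(msg)) msg else TRUE
})

#' A labelled set of images in the canonical pixel domain
#'
#' The container every stage of the pipeline consumes: an `(N, H, W, C)`
#' pixel array with all values in `[0, 1]`, integer labels `1..K`, class
#' names, and the split role the set plays (`train` or `test`).
#'
#' @slot images numeric array `(N, H, W, C)`, pixels in `[0, 1]`.
#' @slot labels integer vector of length `N` with values in `1..K`.
#' @slot classNames character vector of length `K`.
#' @slot split `"train"` or `"test"`.
#' @export
setClass("ImageSet",
  representation(images = "array", labels = "integer",
                 classNames = "character", split = "character"))

setValidity("ImageSet", function(object) {
  msg <- character(0)
  d <- dim(object@images)
  if (length(d) != 4L) msg <- c(msg, "images must be a 4-d (N, H, W, C) array")
  else {
    if (d[1] != length(object@labels))
      msg <- c(msg, "labels length must match the number of images")
    if (!d[4] %in% c(1L, 3L)) msg <- c(msg, "channels must be 1 or 3")
  }
  r <- range(object@images)
  if (is.finite(r[1]) && (r[1] < 0 || r[2] > 1))
    msg <- c(msg, "pixel values must lie in [0, 1]")
  if (length(object@labels) &&
      (min(object@labels) < 1L ||
       max(object@labels) > length(object@classNames)))
    msg <- c(msg, "every label must index a class name")
  if (!object@split %in% c("train", "test"))
    msg <- c(msg, "split must be 'train' or 'test'")
  if (length(msg)) msg else TRUE
})

#' Perturbation-size budget
#'
#' Ties the relative budget `zeta` (a percentage) to an absolute radius
#' `xi` in canonical pixel units through the dataset's average image
#' norm: `xi = zeta / 100 * referenceNorm`. Because `zeta` is a ratio of
#' like norms, budgets expressed through it are invariant to the pixel
#' scale (the same `zeta` means the same relative perturbation whether
#' pixels live in `[0, 1]` or `0..255`).
#'
#' @slot p norm order, `2` or `Inf`.
#' @slot zeta relative budget in percent (>= 0).
#' @slot xi absolute L_p radius in canonical pixel units.
#' @slot referenceNorm the dataset average image L_p norm used for the
#'   conversion.
#' @seealso [perturbationBudget()], [averageImageNorm()]
#' @export
setClass("PerturbationBudget",
  representation(p = "numeric", zeta = "numeric", xi = "numeric",
                 referenceNorm = "numeric"))

setValidity("PerturbationBudget", function(object) {
  msg <- character(0)
  if (!(identical(object@p, 2) || identical(object@p, Inf)))
    msg <- c(msg, "p must be 2 or Inf")
  if (object@zeta < 0) msg <- c(msg, "zeta must be >= 0")
  if (object@xi < 0) msg <- c(msg, "xi must be >= 0")
  if (!identical(object@xi, object@zeta / 100 * object@referenceNorm))
    msg <- c(msg, "xi must equal zeta/100 * referenceNorm exactly")
  if (length(msg)) msg else TRUE
})

#' Attack configuration
#'
#' @slot epsilon FGSM step size in canonical pixel units (> 0).
#' @slot iMax maximum number of full passes over the image set (>= 0).
#' @slot mode `"nontargeted"` or `"targeted"`.
#' @slot targetClass target class index (`1..K`); `NA` unless targeted.
#' @slot seed integer seed controlling the per-pass visiting order.
#' @seealso [attackConfig()], [generateUAP()]
#' @export
setClass("AttackConfig",
  representation(epsilon = "numeric", iMax = "integer", mode = "character",
                 targetClass = "integer", seed = "integer"))

setValidity("AttackConfig", function(object) {
  msg <- character(0)
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
  if (object@iMax < 0L) msg <- c(msg, "iMax must be >= 0")
  if (!object@mode %in% c("nontargeted", "targeted"))
    msg <- c(msg, "mode must be 'nontargeted' or 'targeted'")
  if (object@mode == "targeted" && is.na(object@targetClass))
    msg <- c(msg, "targeted mode requires targetClass")
  if (object@mode == "nontargeted" && !is.na(object@targetClass))
    msg <- c(msg, "targetClass is only meaningful in targeted mode")
  if (length(msg)) msg else TRUE
})

setClassUnion("AttackConfigOrNULL", c("AttackConfig", "NULL"))

#' Universal adversarial perturbation
#'
#' A single image-shaped perturbation `rho` together with the budget it
#' was generated under, the attack configuration (or `NULL` for random
#' controls), the identity of the model it was optimized against, and
#' its achieved L_p norm. The norm never exceeds the budget radius
#' beyond floating-point slack.
#'
#' @slot rho numeric array of shape `(H, W, C)` in canonical pixel units.
#' @slot budget a [PerturbationBudget-class].
#' @slot config the generating [AttackConfig-class], or `NULL` for random
#'   or externally supplied perturbations.
#' @slot sourceModelId id of the attacked model, or `"random"`.
#' @slot achievedNorm the realized `||rho||_p`.
#' @export
setClass("UAP",
  representation(rho = "array", budget = "PerturbationBudget",
                 config = "AttackConfigOrNULL", sourceModelId = "character",
                 achievedNorm = "numeric"))

setValidity("UAP", function(object) {
  msg <- character(0)
  if (length(dim(object@rho)) != 3L)
    msg <- c(msg, "rho must be a 3-d (H, W, C) array")
  if (object@achievedNorm > object@budget@xi * (1 + 1e-6))
    msg <- c(msg, "achieved norm exceeds the budget radius")
  if (length(msg)) msg else TRUE
})

#' Virtual classifier contract
#'
#' Any object usable by the attack, evaluation and defense stages: it
#' must answer [classScores()], [predictLabels()], [lossGradient()],
#' [nClasses()], [inputShape()] and [modelId()]. The package ships two
#' implementations — the trainable [buildSmallCnn()] network and the
#' [functionClassifier()] wrapper for externally supplied score/gradient
#' functions — and any differentiable model can be plugged in by
#' extending this class.
#'
#' @export
setClass("Classifier", representation("VIRTUAL"))

#' @rdname buildSmallCnn
#' @export
setClass("SmallCNN", contains = "Classifier",
  representation(params = "list", shape = "integer", k = "integer",
                 id = "character", trained = "logical"))

#' @rdname functionClassifier
#' @export
setClass("FunctionClassifier", contains = "Classifier",
  representation(scoreFun = "function", gradFun = "functionOrNULL",
                 shape = "integer", k = "integer", id = "character"))

#' Vulnerability evaluation report
#'
#' The result of evaluating one perturbation on one image set with one
#' model: the fooling rate or targeted success rate, the baseline where
#' one is defined (targeted success at `rho = 0`), the row-normalized
#' confusion matrix on the perturbed images, and the dominant classes
#' the predictions collapse into.
#'
#' @slot metric `"fooling_rate"` or `"success_rate"`.
#' @slot value the metric, a fraction in `[0, 1]`.
#' @slot baseline baseline success rate (`NA` for fooling rate).
#' @slot targetClass target class (`NA` for fooling rate).
#' @slot confusion `K x K` row-normalized confusion matrix (rows true,
#'   columns predicted); rows with no observations are all-zero.
#' @slot dominantClasses column indices whose mean column mass exceeds
#'   the dominance threshold, sorted by mass (see [dominantClasses()]).
#' @slot nImages number of evaluated images.
#' @slot uapId id of the evaluated perturbation (`"none"` for clean).
#' @slot split which split was evaluated.
#' @export
setClass("EvaluationReport",
  representation(metric = "character", value = "numeric",
                 baseline = "numeric", targetClass = "integer",
                 confusion = "matrix", dominantClasses = "integer",
                 nImages = "integer", uapId = "character",
                 split = "character"))

setValidity("EvaluationReport", function(object) {
  msg <- character(0)
  if (object@value < 0 || object@value > 1)
    msg <- c(msg, "value must lie in [0, 1]")
  rs <- rowSums(object@confusion)
  bad <- abs(rs - 1) > 1e-9 & rs != 0
  if (any(bad)) msg <- c(msg, "nonzero confusion rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' The optimization recipe: SGD with momentum, a piecewise-constant
#' learning-rate schedule keyed on the epoch number, light geometric
#' augmentation (random rotation and height/width shifts), and optional
#' minority-class oversampling for imbalanced tasks. The defaults are
#' the reference recipe: batch 32, 50 epochs, momentum 0.9, learning
#' rate 0.001 up to epoch 40, 1e-4 for 41-45, 1e-5 after, rotations in
#' `[-5, 5]` degrees and 5% shifts.
#'
#' @slot batchSize minibatch size.
#' @slot epochs number of epochs.
#' @slot momentum SGD momentum coefficient.
#' @slot lrSchedule data.frame with columns `untilEpoch`, `lr`; the rate
#'   for an epoch is the first row with `epoch <= untilEpoch`.
#' @slot augmentRotationDeg rotation range in degrees (`r` means uniform
#'   in `[-r, r]`; 0 disables).
#' @slot augmentShiftFrac shift range as a fraction of image size.
#' @slot oversample resample minority classes with replacement to the
#'   majority count each epoch.
#' @slot seed integer seed for shuffling, augmentation and oversampling.
#' @seealso [trainConfig()], [learningRateAt()]
#' @export
setClass("TrainConfig",
  representation(batchSize = "integer", epochs = "integer",
                 momentum = "numeric", lrSchedule = "data.frame",
                 augmentRotationDeg = "numeric", augmentShiftFrac = "numeric",
                 oversample = "logical", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  s <- object@lrSchedule
  if (!all(c("untilEpoch", "lr") %in% names(s)))
    msg <- c(msg, "lrSchedule needs columns untilEpoch and lr")
  else if (any(s$lr <= 0)) msg <- c(msg, "learning rates must be > 0")
  if (length(msg)) msg else TRUE
})
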
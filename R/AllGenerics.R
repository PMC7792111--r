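#' @include AllClasses.R
NULL

#' Per-class scores for a batch of images
#'
#' Returns the raw (pre-softmax) class scores of a classifier for a batch
#' of images. All other prediction machinery (predicted labels, losses,
#' FGSM gradients) is defined in terms of these scores.
#'
#' @param object a classifier.
#' @param x an [ImageSet-class] or a numeric array of shape `(N, H, W, C)`
#'   (a single `(H, W, C)` image is promoted to a batch of one).
#' @return an `N x K` numeric matrix of scores.
#' @export
setGeneric("classScores", function(object, x) standardGeneric("classScores"))

#' Predicted class labels
#'
#' The argmax of [classScores()] per image, with ties broken toward the
#' lowest class index.
#'
#' @inheritParams classScores
#' @return an integer vector of labels in `1..nClasses(object)`.
#' @export
setGeneric("predictLabels", function(object, x) standardGeneric("predictLabels"))

#' Gradient of the per-image cross-entropy loss w.r.t. input pixels
#'
#' The quantity the fast gradient sign method is built on: for each image
#' the gradient of its own cross-entropy loss (at the supplied label) with
#' respect to its pixels in the canonical `[0, 1]` domain. Gradients are
#' per-image, never averaged over the batch.
#'
#' @inheritParams classScores
#' @param labels integer labels (`1..K`), one per image, at which the
#'   loss is evaluated.
#' @return a numeric array with the same shape as the image batch.
#' @export
setGeneric("lossGradient",
           function(object, x, labels) standardGeneric("lossGradient"))

#' @rdname classifier-accessors
#' @export
setGeneric("nClasses", function(object) standardGeneric("nClasses"))

#' @rdname classifier-accessors
#' @export
setGeneric("inputShape", function(object) standardGeneric("inputShape"))

#' @rdname classifier-accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))

#' Train a classifier on an image set
#'
#' @param object a trainable classifier (see [buildSmallCnn()]).
#' @param trainSet an [ImageSet-class] whose labels cover every class.
#' @param config a [trainConfig()] describing the optimization recipe.
#' @return the trained classifier.
#' @export
setGeneric("trainClassifier",
           function(object, trainSet, config) standardGeneric("trainClassifier"))

#' Generate a universal adversarial perturbation
#'
#' @param object the classifier under attack.
#' @param X the [ImageSet-class] the perturbation is optimized over
#'   (conventionally the training split).
#' @param budget a [perturbationBudget()].
#' @param config an [attackConfig()].
#' @param ... method-specific arguments.
#' @return a [UAP-class] object.
#' @export
setGeneric("generateUAP",
           function(object, X, budget, config, ...) standardGeneric("generateUAP"))

#' @rdname ImageSet-accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname ImageSet-accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname ImageSet-accessors
#' @export
setGeneric("imageSplit", function(x) standardGeneric("imageSplit"))

#' @rdname ImageSet-accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))
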
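#' @include AllClasses.R AllGenerics.R utils.R constructors.R attack.R
NULL

evalPredictions <- function(handle, X, rho) {
  arr <- images(X)
  rhoArr <- if (is.null(rho)) NULL else asRho(rho)
  adv <- if (is.null(rhoArr)) arr else {
    checkShapeMatch(rhoArr, dim(arr)[2:4])
    clip01(arr + array(rep(rhoArr, each = dim(arr)[1]), dim = dim(arr)))
  }
  list(clean = predictLabels(handle, arr), adv = predictLabels(handle, adv))
}

buildConfusion <- function(trueLab, predLab, k, classNames, warn = TRUE) {
  cm <- matrix(0, k, k, dimnames = list(true = classNames,
                                        predicted = classNames))
  for (i in seq_along(trueLab))
    cm[trueLab[i], predLab[i]] <- cm[trueLab[i], predLab[i]] + 1
  rs <- rowSums(cm)
  if (warn && any(rs == 0))
    warning("classes with no observations yield all-zero confusion rows: ",
            paste(classNames[rs == 0], collapse = ", "))
  cm[rs > 0, ] <- cm[rs > 0, , drop = FALSE] / rs[rs > 0]
  cm
}

#' Fooling rate of a perturbation
#'
#' The fraction of images whose prediction changes under the
#' perturbation: `R_f = |X|^-1 sum I(C(x) != C(clip(x + rho)))`. The
#' reference is the clean prediction, never the true label, so a wrong
#' but stable prediction does not count as fooled.
#'
#' @param handle a classifier.
#' @param X an [ImageSet-class].
#' @param rho a [UAP-class] or `(H, W, C)` array.
#' @return an [EvaluationReport-class] with `metric = "fooling_rate"`,
#'   the row-normalized confusion matrix of the perturbed images, and
#'   the dominant classes.
#' @export
foolingRate <- function(handle, X, rho) {
  stopifnot(nImages(X) > 0)
  pr <- evalPredictions(handle, X, rho)
  cm <- buildConfusion(labels(X), pr$adv, nClasses(handle),
                       classNames(X), warn = FALSE)
  new("EvaluationReport", metric = "fooling_rate",
      value = mean(pr$clean != pr$adv), baseline = NA_real_,
      targetClass = NA_integer_, confusion = cm,
      dominantClasses = dominantClasses(cm), nImages = nImages(X),
      uapId = uapIdOf(rho), split = imageSplit(X))
}

#' Targeted attack success rate
#'
#' The fraction of perturbed images classified into the target class:
#' `R_s = |X|^-1 sum I(C(clip(x + rho)) = y)`. The report's `baseline`
#' is the same quantity at `rho = 0` — what the class composition and
#' the classifier already deliver without any attack.
#'
#' @inheritParams foolingRate
#' @param targetClass the attack's target class (`1..K`).
#' @return an [EvaluationReport-class] with `metric = "success_rate"`.
#' @export
successRate <- function(handle, X, rho, targetClass) {
  stopifnot(nImages(X) > 0)
  targetClass <- as.integer(targetClass)
  if (targetClass < 1L || targetClass > nClasses(handle))
    stop("target class outside 1..nClasses")
  pr <- evalPredictions(handle, X, rho)
  cm <- buildConfusion(labels(X), pr$adv, nClasses(handle),
                       classNames(X), warn = FALSE)
  new("EvaluationReport", metric = "success_rate",
      value = mean(pr$adv == targetClass),
      baseline = mean(pr$clean == targetClass),
      targetClass = targetClass, confusion = cm,
      dominantClasses = dominantClasses(cm), nImages = nImages(X),
      uapId = uapIdOf(rho), split = imageSplit(X))
}

#' Row-normalized confusion matrix under a perturbation
#'
#' Cell `(i, j)` is the fraction of class-`i` images (true label)
#' predicted as class `j` on `clip(x + rho)`; rows are true classes,
#' columns predicted. Row normalization makes the matrix readable for
#' imbalanced datasets. Classes absent from `X` give all-zero rows and
#' a warning.
#'
#' @inheritParams foolingRate
#' @param rho a perturbation, or `NULL` for the clean matrix.
#' @return a `K x K` matrix whose nonzero rows sum to 1.
#' @export
confusionMatrix <- function(handle, X, rho = NULL) {
  stopifnot(nImages(X) > 0)
  pr <- evalPredictions(handle, X, rho)
  buildConfusion(labels(X), pr$adv, nClasses(handle), classNames(X))
}

#' Dominant predicted classes of a confusion matrix
#'
#' Nontargeted universal perturbations tend to collapse predictions
#' into a few classes. A class is called dominant when its mean column
#' mass — averaged over the rows with observations — reaches
#' `threshold`. Returned indices are sorted by mass, largest first.
#'
#' @param confusion a row-normalized confusion matrix.
#' @param threshold dominance threshold on mean column mass.
#' @return an integer vector of column (class) indices, possibly empty.
#' @export
dominantClasses <- function(confusion, threshold = 0.5) {
  keep <- rowSums(confusion) > 0
  if (!any(keep)) return(integer(0))
  mass <- colMeans(confusion[keep, , drop = FALSE])
  idx <- which(mass >= threshold)
  as.integer(idx[order(mass[idx], decreasing = TRUE)])
}

#' Cross-model transferability table
#'
#' Cell `(i, j)` is the chosen metric of `uaps[[i]]` (generated against
#' `models[[i]]`) evaluated on `models[[j]]`; the diagonal is each
#' perturbation's direct effectiveness on its source model, off-diagonal
#' cells measure transfer.
#'
#' @param models list of classifiers sharing input shape and class set.
#' @param uaps list of [UAP-class]s, `uaps[[i]]` generated against
#'   `models[[i]]`.
#' @param X the [ImageSet-class] to evaluate on.
#' @param metric `"fooling_rate"` or `"success_rate"`.
#' @param targetClass target class, required for `"success_rate"`.
#' @return an `M x M` matrix with model ids as dimnames.
#' @export
transferabilityMatrix <- function(models, uaps, X,
                                  metric = c("fooling_rate", "success_rate"),
                                  targetClass = NULL) {
  metric <- match.arg(metric)
  stopifnot(length(models) == length(uaps))
  ks <- vapply(models, nClasses, integer(1))
  if (length(unique(ks)) != 1L || ks[1] != length(classNames(X)))
    stop("all models must share one class set matching the dataset")
  m <- length(models)
  ids <- vapply(models, modelId, character(1))
  out <- matrix(NA_real_, m, m, dimnames = list(uap = ids, model = ids))
  for (i in seq_len(m))
    for (j in seq_len(m))
      out[i, j] <- if (metric == "fooling_rate")
        foolingRate(models[[j]], X, uaps[[i]])@value
      else successRate(models[[j]], X, uaps[[i]], targetClass)@value
  out
}
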
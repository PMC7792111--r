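#' @include AllClasses.R AllGenerics.R utils.R constructors.R classifier.R
NULL

#' One fast-gradient-sign step
#'
#' Nontargeted mode ascends the loss at the true label:
#' `+epsilon * sign(dL(x, label)/dx)`. Targeted mode descends the loss
#' at the target class: `-epsilon * sign(dL(x, target)/dx)`. Components
#' with zero gradient yield zero perturbation.
#'
#' @param handle a classifier with gradients.
#' @param images an [ImageSet-class] or `(N, H, W, C)` array.
#' @param labels true labels (nontargeted mode).
#' @param epsilon step size (> 0).
#' @param mode `"nontargeted"` or `"targeted"`.
#' @param targetClass target class (`1..K`), targeted mode only.
#' @return a perturbation array with the batch's shape, entries in
#'   `{-epsilon, 0, +epsilon}`.
#' @export
fgsmStep <- function(handle, images, labels = NULL, epsilon,
                     mode = c("nontargeted", "targeted"),
                     targetClass = NULL) {
  mode <- match.arg(mode)
  stopifnot(epsilon > 0)
  arr <- asImageArray(images)
  n <- dim(arr)[1]
  if (mode == "targeted") {
    if (is.null(targetClass)) stop("targeted mode requires targetClass")
    g <- lossGradient(handle, arr, rep(as.integer(targetClass), n))
    -epsilon * sign(g)
  } else {
    if (is.null(labels)) {
      if (is(images, "ImageSet")) labels <- labels(images)
      else stop("nontargeted mode requires true labels")
    }
    g <- lossGradient(handle, arr, labels)
    epsilon * sign(g)
  }
}

#' Project a perturbation onto the L_p ball of radius xi
#'
#' `p = Inf` clamps elementwise to `[-xi, xi]`; `p = 2` rescales onto
#' the sphere when the norm exceeds `xi`. The projection is idempotent
#' and is the identity on any perturbation already inside the ball.
#'
#' @param rho a numeric array.
#' @param p `2` or `Inf`.
#' @param xi ball radius (>= 0).
#' @return the projected array.
#' @export
projectLp <- function(rho, p, xi) {
  stopifnot(xi >= 0)
  if (identical(p, Inf)) return(pmin(pmax(rho, -xi), xi))
  nr <- lpNorm(rho, 2)
  if (nr <= xi) rho else rho * (xi / nr)
}

#' Add a universal perturbation to a batch and clip
#'
#' Returns `clip(x + rho)` into the canonical `[0, 1]` pixel domain.
#'
#' @param images an [ImageSet-class] or image array (batched or single).
#' @param rho a [UAP-class] or `(H, W, C)` array.
#' @return the perturbed object, same type as `images`.
#' @export
applyUAP <- function(images, rho) {
  rho <- asRho(rho)
  if (is(images, "ImageSet")) {
    arr <- images@images
    checkShapeMatch(rho, dim(arr)[2:4])
    out <- images
    out@images <- clip01(arr + array(rep(rho, each = dim(arr)[1]),
                                     dim = dim(arr)))
    return(out)
  }
  arr <- asImageArray(images)
  checkShapeMatch(rho, dim(arr)[2:4])
  out <- clip01(arr + array(rep(rho, each = dim(arr)[1]), dim = dim(arr)))
  if (length(dim(images)) == 3L) array(out, dim = dim(images)) else out
}

# shared setup for both generateUAP paths: validation, seeded per-pass
# visiting orders, clean reference predictions and gradient labels
uapSetup <- function(object, X, budget, config) {
  stopifnot(is(X, "ImageSet"), is(budget, "PerturbationBudget"),
            is(config, "AttackConfig"))
  validObject(budget); validObject(config)
  n <- nImages(X)
  if (n < 1L) stop("image set is empty")
  targeted <- config@mode == "targeted"
  if (targeted &&
      (config@targetClass < 1L || config@targetClass > nClasses(object)))
    stop("target class outside 1..nClasses")
  orders <- withSeed(config@seed, {
    if (config@iMax > 0L)
      vapply(seq_len(config@iMax), function(i) sample.int(n), integer(n))
    else matrix(integer(0), nrow = n, ncol = 0L)
  })
  if (config@iMax > 0L) dim(orders) <- c(n, config@iMax)
  list(n = n, targeted = targeted, orders = orders,
       cleanPred = predictLabels(object, X),
       gradLabels = if (targeted) rep(config@targetClass, n) else labels(X))
}

#' @describeIn generateUAP reference implementation for any classifier
#'   obeying the contract: starts at `rho = 0` and, for `iMax` shuffled
#'   passes over the set, adds an FGSM step at `clip(x + rho)` for every
#'   image not yet defeated (nontargeted: still classified as its clean
#'   prediction; targeted: not yet classified as the target), then
#'   re-projects onto the budget ball.
#' @export
setMethod("generateUAP", "Classifier", function(object, X, budget, config) {
  st <- uapSetup(object, X, budget, config)
  shape <- dim(images(X))[2:4]
  rho <- array(0, dim = shape)
  arr <- images(X)
  for (pass in seq_len(config@iMax)) {
    for (i in st$orders[, pass]) {
      xi <- arr[i, , , , drop = FALSE]
      dim(xi) <- shape
      xa <- clip01(xi + rho)
      pred <- predictLabels(object, array(xa, dim = c(1L, shape)))
      defeated <- if (st$targeted) pred == config@targetClass
                  else pred != st$cleanPred[i]
      if (defeated) next
      step <- fgsmStep(object, array(xa, dim = c(1L, shape)),
                       labels = st$gradLabels[i],
                       epsilon = config@epsilon, mode = config@mode,
                       targetClass = if (st$targeted) config@targetClass)
      rho <- projectLp(rho + array(step, dim = shape), budget@p, budget@xi)
    }
  }
  newUAP(rho, budget, config, modelId(object))
})

#' @describeIn generateUAP fast path for the built-in small CNN; the
#'   whole pass loop runs in compiled code and reproduces the reference
#'   implementation's result for the same seed.
#' @export
setMethod("generateUAP", "SmallCNN", function(object, X, budget, config) {
  st <- uapSetup(object, X, budget, config)
  s <- object@shape
  checkInputShape(object, images(X))
  res <- cpp_uap_passes(object@params, flattenBatch(images(X)),
                        st$gradLabels - 1L, st$cleanPred - 1L,
                        numeric(prod(s)), s[1], s[2], s[3],
                        config@epsilon, budget@xi, budget@p,
                        st$targeted,
                        if (st$targeted) config@targetClass - 1L else -1L,
                        st$orders - 1L)
  rho <- array(res$rho, dim = s)
  newUAP(rho, budget, config, modelId(object))
})

#' Sample a random perturbation from the L_p sphere
#'
#' The control perturbation matched in size to an optimized UAP: for
#' `p = 2` an isotropic Gaussian draw rescaled to `||rho||_2 = xi`
#' (uniform on the sphere); for `p = Inf` each component drawn uniformly
#' from `{-xi, +xi}` (the uniform-sign convention for the L-infinity
#' sphere).
#'
#' @param imageShape integer `(H, W, C)`.
#' @param p `2` or `Inf` (ignored when `budget` is given).
#' @param xi sphere radius (ignored when `budget` is given).
#' @param seed integer seed.
#' @param budget optional [PerturbationBudget-class] supplying `p` and
#'   `xi` and recorded on the result.
#' @return a [UAP-class] with `sourceModelId = "random"`.
#' @export
sampleRandomUAP <- function(imageShape, p = 2, xi = NULL, seed = 1L,
                            budget = NULL) {
  if (!is.null(budget)) { p <- budget@p; xi <- budget@xi }
  if (is.null(xi) || xi < 0) stop("xi must be a nonnegative radius")
  d <- prod(imageShape)
  rho <- withSeed(seed, {
    if (identical(p, Inf)) sample(c(-xi, xi), d, replace = TRUE)
    else {
      g <- stats::rnorm(d)
      if (xi == 0) g * 0 else g * (xi / sqrt(sum(g^2)))
    }
  })
  if (is.null(budget))
    budget <- perturbationBudget(p = p, zeta = 100, referenceNorm = xi)
  newUAP(array(rho, dim = imageShape), budget, NULL, "random")
}

#' Serialize a UAP as plain text (CSV array + JSON sidecar)
#'
#' @param uap a [UAP-class].
#' @param path output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
saveUAP <- function(uap, path) {
  d <- dim(uap@rho)
  utils::write.csv(data.frame(value = as.vector(uap@rho)),
                   paste0(path, ".csv"), row.names = FALSE)
  meta <- list(shape = d, p = if (is.infinite(uap@budget@p)) "inf" else
                 uap@budget@p,
               zeta = uap@budget@zeta, xi = uap@budget@xi,
               referenceNorm = uap@budget@referenceNorm,
               achievedNorm = uap@achievedNorm,
               sourceModelId = uap@sourceModelId)
  if (!is.null(uap@config)) {
    meta <- c(meta, list(epsilon = uap@config@epsilon,
                         iMax = uap@config@iMax, mode = uap@config@mode,
                         seed = uap@config@seed))
    if (!is.na(uap@config@targetClass))
      meta$targetClass <- uap@config@targetClass
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a UAP written by [saveUAP()]
#'
#' @param path path prefix used when saving.
#' @return a [UAP-class].
#' @export
loadUAP <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- utils::read.csv(paste0(path, ".csv"))$value
  p <- if (identical(meta$p, "inf")) Inf else as.numeric(meta$p)
  budget <- perturbationBudget(p = p, zeta = meta$zeta,
                               referenceNorm = meta$referenceNorm)
  config <- if (!is.null(meta$mode))
    attackConfig(epsilon = meta$epsilon, iMax = meta$iMax, mode = meta$mode,
                 targetClass = meta$targetClass %||% NA_integer_,
                 seed = meta$seed)
  newUAP(array(vals, dim = unlist(meta$shape)), budget, config,
         meta$sourceModelId)
}
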
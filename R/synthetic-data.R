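#' @include AllClasses.R AllGenerics.R utils.R constructors.R
NULL

# --- class-conditional pattern generators ---------------------------------
# Each returns an H x W matrix in roughly [0, 1] before noise/clipping.
# Class identity is carried by a low-frequency, large-scale feature so a
# small CNN can learn it quickly; per-image jitter keeps the task
# non-trivial.

# Lesion-style design: class 1 is a lesion-free background (the "normal"
# class most medical tasks have), classes 2..K carry a subtle Gaussian
# bright spot at a class-specific position. The low lesion contrast
# (0.12 against pixel noise of comparable size) keeps decision margins
# moderate, as they are for real diagnostic classes.
blobPattern <- function(h, w, k, K) {
  side <- min(h, w)
  base <- matrix(0.35, h, w)
  if (k == 1L) return(base)
  ang <- 2 * pi * (k - 2) / max(1, K - 1)
  cy <- h / 2 + 0.22 * side * sin(ang) + stats::runif(1, -0.05, 0.05) * side
  cx <- w / 2 + 0.22 * side * cos(ang) + stats::runif(1, -0.05, 0.05) * side
  sigma <- 0.09 * side * stats::runif(1, 0.85, 1.15)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (yy - cy)^2 + (xx - cx)^2
  base + 0.12 * exp(-d2 / (2 * sigma^2))
}

stripePattern <- function(h, w, k, K) {
  freq <- 2 + 1.5 * (k - 1)
  theta <- pi * (k - 1) / K
  phase <- stats::runif(1, 0, 2 * pi)
  yy <- matrix(seq_len(h) / h, h, w)
  xx <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  u <- xx * cos(theta) + yy * sin(theta)
  0.5 + 0.35 * sin(2 * pi * freq * u + phase)
}

texturePattern <- function(h, w, k, K) {
  # band-pass filtered white noise; the pass-band radius encodes the class
  z <- matrix(stats::rnorm(h * w), h, w)
  fz <- stats::fft(z)
  fy <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1)) / h
  fx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / w
  r <- sqrt(outer(fy^2, fx^2, `+`))
  r0 <- 0.04 + 0.10 * (k - 1) / max(1, K - 1)
  filt <- exp(-((r - r0) / 0.03)^2)
  t <- Re(stats::fft(fz * filt, inverse = TRUE)) / (h * w)
  t <- (t - mean(t)) / (stats::sd(t) + 1e-12)
  0.5 + 0.15 * t
}

classTint <- function(k, K, channels) {
  if (channels == 1L) return(1)
  0.55 + 0.45 * cos(2 * pi * ((k - 1) / K - (seq_len(channels) - 1) / 3))
}

makeClassImage <- function(spec, k) {
  h <- spec@imageHeight; w <- spec@imageWidth; K <- spec@nClasses
  base <- switch(spec@patternFamily,
                 blob = blobPattern(h, w, k, K),
                 stripe = stripePattern(h, w, k, K),
                 texture = texturePattern(h, w, k, K))
  tint <- classTint(k, K, spec@channels)
  img <- array(0, dim = c(h, w, spec@channels))
  for (ch in seq_len(spec@channels)) img[, , ch] <- base * tint[ch]
  img <- img + stats::rnorm(length(img), sd = spec@noiseSd)
  clip01(img)
}

generateSplit <- function(spec, n, split) {
  counts <- allocateCounts(n, spec@classProportions)
  lab <- rep.int(seq_len(spec@nClasses), counts)
  arr <- array(0, dim = c(n, spec@imageHeight, spec@imageWidth,
                          spec@channels))
  for (i in seq_len(n)) arr[i, , , ] <- makeClassImage(spec, lab[i])
  ord <- sample.int(n)
  cn <- if (length(spec@classNames)) spec@classNames
        else sprintf("class%02d", seq_len(spec@nClasses))
  imageSet(arr[ord, , , , drop = FALSE], lab[ord], cn, split)
}

#' Generate a seeded synthetic classification dataset
#'
#' Draws a train and a test [ImageSet-class] from the class-conditional
#' pattern distributions described by the spec. Per-class counts of each
#' split are the proportional allocation
#' `round(n * proportion_k / sum(proportions))` with the remainder
#' absorbed by the largest-weight class, so counts always sum to the
#' requested split size. Identical spec and seed reproduce bitwise
#' identical arrays.
#'
#' @param spec a [syntheticTaskSpec()].
#' @return a list with elements `train` and `test`.
#' @examples
#' ds <- generateDataset(syntheticTaskSpec(nClasses = 2, nTrain = 8,
#'                                         nTest = 4, imageHeight = 16,
#'                                         imageWidth = 16))
#' table(labels(ds$train))
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticTaskSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    train <- generateSplit(spec, spec@nTrain, "train")
    test <- generateSplit(spec, spec@nTest, "test")
    list(train = train, test = test)
  })
}

#' Average image L_p norm of a dataset
#'
#' The reference quantity that converts a relative perturbation budget
#' `zeta` into an absolute radius `xi`: the mean over images of
#' `||x||_p`, with `p = Inf` the maximum absolute pixel value and
#' `p = 2` the Euclidean norm of the flattened image.
#'
#' @param dataset an [ImageSet-class].
#' @param p `2` or `Inf`.
#' @return a nonnegative scalar.
#' @export
averageImageNorm <- function(dataset, p = 2) {
  arr <- asImageArray(dataset)
  n <- dim(arr)[1]
  if (n == 0) stop("dataset is empty")
  mean(vapply(seq_len(n), function(i) lpNorm(arr[i, , , ], p), numeric(1)))
}

#' Resize every image in a set
#'
#' Nearest-neighbour resampling to a new height/width (the same
#' interpolation convention the training augmentation uses). Useful for
#' bringing externally loaded folders onto a model's input shape.
#'
#' @param dataset an [ImageSet-class].
#' @param height,width target size in pixels.
#' @return a resized [ImageSet-class].
#' @export
resizeImages <- function(dataset, height, width) {
  stopifnot(height >= 1, width >= 1)
  arr <- images(dataset)
  d <- dim(arr)
  si <- pmin(pmax(round(seq_len(height) * d[2] / height), 1L), d[2])
  sj <- pmin(pmax(round(seq_len(width) * d[3] / width), 1L), d[3])
  out <- arr[, si, sj, , drop = FALSE]
  imageSet(out, labels(dataset), classNames(dataset), imageSplit(dataset))
}

#' Write / read a task specification as YAML
#'
#' @param spec a [syntheticTaskSpec()].
#' @param path YAML file path.
#' @return `writeTaskSpec` returns `path` invisibly; `readTaskSpec`
#'   returns the [SyntheticTaskSpec-class].
#' @export
writeTaskSpec <- function(spec, path) {
  yaml::write_yaml(list(
    nClasses = spec@nClasses, classProportions = spec@classProportions,
    imageHeight = spec@imageHeight, imageWidth = spec@imageWidth,
    channels = spec@channels, patternFamily = spec@patternFamily,
    noiseSd = spec@noiseSd, nTrain = spec@nTrain, nTest = spec@nTest,
    classNames = as.list(spec@classNames), seed = spec@seed), path)
  invisible(path)
}

#' @rdname writeTaskSpec
#' @export
readTaskSpec <- function(path) {
  y <- yaml::read_yaml(path)
  syntheticTaskSpec(nClasses = y$nClasses,
                    classProportions = unlist(y$classProportions),
                    imageHeight = y$imageHeight, imageWidth = y$imageWidth,
                    channels = y$channels, patternFamily = y$patternFamily,
                    noiseSd = y$noiseSd, nTrain = y$nTrain, nTest = y$nTest,
                    classNames = as.character(unlist(y$classNames)),
                    seed = y$seed)
}

#' Read a directory-per-class PNG folder as an ImageSet
#'
#' Class subdirectories are assigned label indices in lexicographic
#' (C-locale) order of their names. Pixel values are rescaled to the
#' canonical `[0, 1]` domain.
#'
#' @param path folder containing one subdirectory per class.
#' @param channels force 1 (grayscale; RGB files are averaged) or 3
#'   (RGB; grayscale files are replicated); default keeps the channel
#'   count of the first image.
#' @param split split role recorded on the result.
#' @return an [ImageSet-class].
#' @export
loadImageFolder <- function(path, channels = NULL, split = "train") {
  dirs <- sort(list.dirs(path, recursive = FALSE, full.names = TRUE),
               method = "radix")
  if (!length(dirs)) stop("no class subdirectories under ", path)
  cn <- basename(dirs)
  imgs <- list(); lab <- integer(0)
  for (k in seq_along(dirs)) {
    files <- sort(list.files(dirs[k], pattern = "\\.png$",
                             full.names = TRUE), method = "radix")
    if (!length(files)) stop("empty class directory: ", dirs[k])
    for (f in files) {
      px <- tryCatch(png::readPNG(f),
                     error = function(e) stop("unreadable PNG file: ", f,
                                              " (", conditionMessage(e), ")"))
      if (length(dim(px)) == 2L) dim(px) <- c(dim(px), 1L)
      if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
      if (is.null(channels)) channels <- dim(px)[3]
      if (channels == 1L && dim(px)[3] == 3L) {
        px <- array(rowMeans(matrix(px, ncol = 3L)), dim = c(dim(px)[1:2], 1L))
      } else if (channels == 3L && dim(px)[3] == 1L) {
        px <- array(rep(px, 3L), dim = c(dim(px)[1:2], 3L))
      }
      imgs[[length(imgs) + 1L]] <- px
      lab <- c(lab, k)
    }
  }
  d <- dim(imgs[[1]])
  arr <- array(0, dim = c(length(imgs), d))
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d))
      stop("images do not share one shape")
    arr[i, , , ] <- imgs[[i]]
  }
  imageSet(arr, lab, cn, split)
}

#' Write an ImageSet as a directory-per-class PNG folder
#'
#' Creates one subdirectory per class name, writes 8-bit PNGs (so a
#' round trip preserves pixels to within 1/255 quantization and labels
#' exactly), and a `manifest.csv` listing filename, label and split.
#'
#' @param dataset an [ImageSet-class].
#' @param path output folder (created if missing).
#' @return `path`, invisibly.
#' @export
saveImageFolder <- function(dataset, path) {
  stopifnot(is(dataset, "ImageSet"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  arr <- dataset@images
  rows <- vector("list", nImages(dataset))
  for (i in seq_len(nImages(dataset))) {
    cls <- dataset@classNames[dataset@labels[i]]
    dir.create(file.path(path, cls), showWarnings = FALSE)
    img <- arr[i, , , ]
    if (length(dim(img)) == 2L || dim(arr)[4] == 1L)
      img <- matrix(arr[i, , , 1L], dim(arr)[2], dim(arr)[3])
    fn <- file.path(cls, sprintf("img_%05d.png", i))
    png::writePNG(img, file.path(path, fn))
    rows[[i]] <- data.frame(filename = fn, label = dataset@labels[i],
                            class = cls, split = dataset@split)
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(path)
}
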
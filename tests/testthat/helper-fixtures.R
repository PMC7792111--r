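# Small shared fixtures built in code.

# a tiny task for fast unit tests (16x16 images)
tinySpec <- function(nClasses = 3L, channels = 1L, seed = 7L,
                     nTrain = 24L, nTest = 12L, family = "blob") {
  syntheticTaskSpec(nClasses = nClasses, imageHeight = 16L, imageWidth = 16L,
                    channels = channels, patternFamily = family,
                    noiseSd = 0.05, nTrain = nTrain, nTest = nTest,
                    seed = seed)
}

tinyBatch <- function(n = 4L, h = 16L, w = 16L, c = 1L, seed = 1L) {
  set.seed(seed)
  array(runif(n * h * w * c), dim = c(n, h, w, c))
}

# a classifier whose prediction is read off a stored lookup: scores are a
# fixed random linear map of the flattened pixels, so predictions are
# deterministic, nontrivial, and sensitive to perturbations
projectionClassifier <- function(shape, k, seed = 1L) {
  d <- prod(shape)
  set.seed(seed)
  P <- matrix(rnorm(d * k), d, k)
  functionClassifier(function(arr) {
    m <- matrix(aperm(arr, c(2, 3, 4, 1)), nrow = d)
    t(crossprod(P, m))
  }, inputShape = shape, nClasses = k, id = sprintf("proj-%d", seed))
}

# a perfectly accurate classifier for datasets whose class is encoded in
# the mean pixel intensity: class k images have mean approx (k - 0.5) / K
meanCodedDataset <- function(k, n, shape = c(8L, 8L, 1L), split = "test") {
  lab <- rep(seq_len(k), length.out = n)
  arr <- array(0, dim = c(n, shape))
  for (i in seq_len(n)) arr[i, , , ] <- (lab[i] - 0.5) / k
  imageSet(arr, lab, sprintf("c%d", seq_len(k)), split)
}

meanCodedClassifier <- function(k, shape = c(8L, 8L, 1L)) {
  functionClassifier(function(arr) {
    mu <- apply(arr, 1, mean)
    centers <- (seq_len(k) - 0.5) / k
    -abs(outer(mu, centers, `-`))
  }, inputShape = shape, nClasses = k, id = "mean-coded")
}
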
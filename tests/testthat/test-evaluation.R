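# naive per-image loop oracles, kept deliberately separate from the
# package's vectorized implementations
oracleFooling <- function(clean, adv) {
  n <- length(clean); hits <- 0
  for (i in seq_len(n)) if (clean[i] != adv[i]) hits <- hits + 1
  hits / n
}
oracleSuccess <- function(adv, target) {
  n <- length(adv); hits <- 0
  for (i in seq_len(n)) if (adv[i] == target) hits <- hits + 1
  hits / n
}
oracleConfusion <- function(true, pred, k) {
  cm <- matrix(0, k, k)
  for (i in seq_along(true)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1
  for (r in seq_len(k)) if (sum(cm[r, ]) > 0) cm[r, ] <- cm[r, ] / sum(cm[r, ])
  cm
}

test_that("fooling rate matches its formula on hand-checked cases", {
  shape <- c(8L, 8L, 1L)
  ds <- meanCodedDataset(2, 4, shape)
  cls <- meanCodedClassifier(2, shape)

  # rho = 0: identical predictions, R_f = 0
  expect_equal(foolingRate(cls, ds, array(0, dim = shape))@value, 0)

  # a perturbation flipping exactly the two class-1 images: clean
  # (1,2,1,2) vs adversarial (2,2,2,2) -> R_f = 0.5
  rho <- array(0.5, dim = shape)
  rep1 <- foolingRate(cls, ds, rho)
  clean <- predictLabels(cls, ds)
  adv <- predictLabels(cls, applyUAP(ds, rho))
  expect_equal(rep1@value, oracleFooling(clean, adv))
  expect_equal(rep1@value, 0.5)
})

test_that("metrics equal loop oracles on randomized cases", {
  shape <- c(6L, 8L, 1L)  # divisible-by-8 not required for external models
  set.seed(11)
  for (case in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(10:30, 1)
    cls <- projectionClassifier(shape, k, seed = case)
    arr <- array(runif(n * prod(shape)), dim = c(n, shape))
    ds <- imageSet(arr, sample(k, n, replace = TRUE),
                   sprintf("c%d", 1:k), "test")
    rho <- array(rnorm(prod(shape), sd = 0.1), dim = shape)
    clean <- predictLabels(cls, ds)
    adv <- predictLabels(cls, applyUAP(ds, rho))

    expect_identical(foolingRate(cls, ds, rho)@value,
                     oracleFooling(clean, adv))
    tgt <- sample(k, 1)
    sr <- successRate(cls, ds, rho, tgt)
    expect_identical(sr@value, oracleSuccess(adv, tgt))
    expect_identical(sr@baseline, oracleSuccess(clean, tgt))
    expect_identical(suppressWarnings(confusionMatrix(cls, ds, rho)),
                     {
                       cm <- oracleConfusion(labels(ds), adv, k)
                       dimnames(cm) <- list(true = sprintf("c%d", 1:k),
                                            predicted = sprintf("c%d", 1:k))
                       cm
                     })
  }
})

test_that("success-rate baseline identities hold exactly", {
  for (k in c(2L, 4L)) {
    ds <- meanCodedDataset(k, 8L * k)
    cls <- meanCodedClassifier(k)
    rho0 <- array(0, dim = c(8, 8, 1))
    for (tgt in seq_len(k)) {
      sr <- successRate(cls, ds, rho0, tgt)
      expect_identical(sr@value, 1 / k)       # perfectly accurate, balanced
      expect_identical(sr@baseline, sr@value)  # rho = 0 IS the baseline
    }
  }
})

test_that("confusion matrices are row-normalized with true rows", {
  shape <- c(8L, 8L, 1L)
  ds <- meanCodedDataset(3, 9, shape)
  cls <- meanCodedClassifier(3, shape)
  cm <- confusionMatrix(cls, ds)
  expect_equal(cm, diag(3), ignore_attr = TRUE)  # perfect classifier

  # counts row (6 predicted class 1, 2 predicted class 2) -> (0.75, 0.25)
  cmRow <- oracleConfusion(rep(1L, 8), c(rep(1L, 6), rep(2L, 2)), 2)
  expect_equal(cmRow[1, ], c(0.75, 0.25))

  # nonzero rows always sum to 1
  rho <- array(0.3, dim = shape)
  cm2 <- confusionMatrix(cls, ds, rho)
  expect_true(all(abs(rowSums(cm2)[rowSums(cm2) > 0] - 1) < 1e-9))

  # empty true class warns and yields a zero row
  sub <- ds[labels(ds) != 2L]
  expect_warning(cmE <- confusionMatrix(cls, sub), "all-zero")
  expect_true(all(cmE[2, ] == 0))
})

test_that("dominant classes are found by mean column mass", {
  # identity matrix, K >= 3: mean column mass 1/K < 0.5 -> none dominant
  expect_identical(dominantClasses(diag(4)), integer(0))

  # total collapse onto class 3
  cm <- matrix(0, 3, 3); cm[, 3] <- 1
  expect_identical(dominantClasses(cm), 3L)

  # column masses (0.6, 0.3, 0.1) -> only class 1
  cm <- rbind(c(0.6, 0.3, 0.1), c(0.6, 0.3, 0.1), c(0.6, 0.3, 0.1))
  expect_identical(dominantClasses(cm), 1L)

  # masses above threshold come back sorted by mass, descending
  cm <- rbind(c(0.5, 0.5, 0), c(0.4, 0.6, 0))
  expect_identical(dominantClasses(cm, threshold = 0.4), c(2L, 1L))
})

test_that("fooling rate ignores true labels; success rate ignores
           permutations of non-target classes", {
  shape <- c(6L, 8L, 1L)
  cls <- projectionClassifier(shape, 3, seed = 5)
  set.seed(6)
  arr <- array(runif(12 * prod(shape)), dim = c(12, shape))
  rho <- array(rnorm(prod(shape), sd = 0.05), dim = shape)
  ds1 <- imageSet(arr, sample(3, 12, replace = TRUE), c("a", "b", "c"))
  ds2 <- imageSet(arr, sample(3, 12, replace = TRUE), c("a", "b", "c"))
  expect_identical(foolingRate(cls, ds1, rho)@value,
                   foolingRate(cls, ds2, rho)@value)
  expect_identical(successRate(cls, ds1, rho, 2L)@value,
                   successRate(cls, ds2, rho, 2L)@value)
})

test_that("transferability tables are metric-consistent", {
  ds <- generateDataset(tinySpec(nClasses = 2, nTrain = 12, nTest = 8))
  nets <- lapply(1:2, function(s)
    buildSmallCnn(c(16, 16, 1), nClasses = 2, seed = s))
  budget <- perturbationBudget(p = 2, zeta = 5, dataset = ds$train)
  uaps <- lapply(1:2, function(i)
    generateUAP(nets[[i]], ds$train, budget,
                attackConfig(epsilon = 0.01, iMax = 1, seed = i)))

  tm <- transferabilityMatrix(nets, uaps, ds$test, "fooling_rate")
  expect_identical(dim(tm), c(2L, 2L))
  for (i in 1:2)
    expect_identical(tm[i, i],
                     foolingRate(nets[[i]], ds$test, uaps[[i]])@value)

  # a single model with its own UAP: 1x1 table equal to direct evaluation
  t1 <- transferabilityMatrix(nets[1], uaps[1], ds$test, "fooling_rate")
  expect_identical(t1[1, 1],
                   foolingRate(nets[[1]], ds$test, uaps[[1]])@value)

  # the zero perturbation fools nothing anywhere
  zero <- sampleRandomUAP(c(16L, 16L, 1L), p = 2, xi = 0, seed = 1)
  tz <- transferabilityMatrix(nets, list(zero, zero), ds$test,
                              "fooling_rate")
  expect_true(all(tz == 0))
})
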
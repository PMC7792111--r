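test_that("fgsm steps are signed gradients with the documented signs", {
  shape <- c(8L, 8L, 1L)
  # a gradient function returning a fixed pattern with +, - and 0 entries
  gpat <- array(0, dim = c(1, shape))
  gpat[1, 1, 1, 1] <- 3; gpat[1, 2, 1, 1] <- -2
  cls <- functionClassifier(function(arr) matrix(0, dim(arr)[1], 2),
                            shape, 2,
                            gradFun = function(arr, labels)
                              array(rep(gpat, dim(arr)[1] / 1),
                                    dim = dim(arr)),
                            id = "fixed-grad")
  x <- array(0.5, dim = c(1, shape))

  step <- fgsmStep(cls, x, labels = 1L, epsilon = 0.1)
  expect_equal(step[1, 1, 1, 1], 0.1)
  expect_equal(step[1, 2, 1, 1], -0.1)
  expect_equal(step[1, 3, 3, 1], 0)  # zero gradient -> zero step

  # targeted is the negated sign of the target-class loss gradient
  tstep <- fgsmStep(cls, x, epsilon = 0.1, mode = "targeted",
                    targetClass = 2L)
  expect_equal(tstep[1, 1, 1, 1], -0.1)
  expect_equal(tstep[1, 2, 1, 1], 0.1)
  expect_true(all(tstep %in% c(-0.1, 0, 0.1)))

  expect_error(fgsmStep(cls, x, epsilon = 0.1, mode = "targeted"),
               "targetClass")
})

test_that("projectLp clamps, rescales, and is idempotent", {
  # elementwise clamp for p = Inf
  rho <- array(c(0.2, -0.05), dim = c(2, 1, 1))
  out <- projectLp(rho, Inf, 0.1)
  expect_equal(as.vector(out), c(0.1, -0.05))

  # L2 rescale keeps direction, halves the norm
  set.seed(1)
  rho <- array(rnorm(32), dim = c(4, 8, 1))
  xi <- lpNorm(rho, 2) / 2
  out <- projectLp(rho, 2, xi)
  expect_equal(lpNorm(out, 2), xi)
  expect_equal(out / lpNorm(out, 2), rho / lpNorm(rho, 2))

  # identity inside the ball; idempotence everywhere
  for (p in list(2, Inf)) {
    inside <- projectLp(rho, p, lpNorm(rho, p) * 2)
    expect_identical(inside, rho)
    once <- projectLp(rho, p, lpNorm(rho, p) * 0.3)
    expect_equal(projectLp(once, p, lpNorm(rho, p) * 0.3), once)
  }
})

test_that("applyUAP adds and clips into the canonical domain", {
  x <- array(c(0.95, 0.05, 0.5), dim = c(1, 3, 1, 1))
  rho <- array(c(0.2, -0.2, 0), dim = c(3, 1, 1))
  out <- applyUAP(x, rho)
  expect_equal(as.vector(out), c(1, 0, 0.5))

  # rho = 0 leaves images unchanged
  expect_identical(applyUAP(x, rho * 0), x)

  expect_error(applyUAP(x, array(0, dim = c(4, 1, 1))), "shape")
})

test_that("generateUAP respects its budget across randomized configs", {
  ds <- generateDataset(tinySpec(nClasses = 3, nTrain = 12, nTest = 3))
  net <- buildSmallCnn(c(16, 16, 1), nClasses = 3, seed = 1)
  set.seed(42)
  for (rep in 1:6) {
    p <- sample(list(2, Inf), 1)[[1]]
    zeta <- runif(1, 0.5, 10)
    budget <- perturbationBudget(p = p, zeta = zeta, dataset = ds$train)
    cfg <- attackConfig(epsilon = runif(1, 0.001, 0.05),
                        iMax = sample(0:3, 1),
                        seed = sample(1000, 1))
    uap <- generateUAP(net, ds$train, budget, cfg)
    expect_lte(uap@achievedNorm, budget@xi * (1 + 1e-6))
  }
})

test_that("iMax = 0 returns the zero perturbation with zero fooling", {
  ds <- generateDataset(tinySpec(nClasses = 2, nTrain = 8, nTest = 4))
  net <- buildSmallCnn(c(16, 16, 1), nClasses = 2, seed = 1)
  budget <- perturbationBudget(p = 2, zeta = 4, dataset = ds$train)
  uap <- generateUAP(net, ds$train, budget, attackConfig(iMax = 0))
  expect_true(all(uap@rho == 0))
  expect_equal(foolingRate(net, ds$test, uap)@value, 0)
})

test_that("a constant classifier is never defeated and rho stays zero", {
  shape <- c(8L, 8L, 1L)
  cls <- functionClassifier(
    function(arr) matrix(rep(c(1, 0), each = dim(arr)[1]), dim(arr)[1], 2),
    shape, 2,
    gradFun = function(arr, labels) array(0, dim = dim(arr)),
    id = "constant")
  ds <- meanCodedDataset(2, 6, shape)
  budget <- perturbationBudget(p = 2, zeta = 5, dataset = ds)
  uap <- generateUAP(cls, ds, budget, attackConfig(iMax = 2))
  # every image stays classified as class 1 so it is never "defeated";
  # updates use the zero gradient, so rho remains exactly zero
  expect_true(all(uap@rho == 0))
  expect_equal(foolingRate(cls, ds, uap)@value, 0)
})

test_that("a pass over already-defeated images leaves rho unchanged", {
  shape <- c(8L, 8L, 1L)
  # classifier that flips its prediction under any nonzero perturbation
  # of pixel [1, 1]: class = 1 if pixel <= 0.5 else 2
  cls <- functionClassifier(function(arr) {
    v <- arr[, 1, 1, 1]
    cbind(ifelse(v <= 0.5, 1, 0), ifelse(v > 0.5, 1, 0))
  }, shape, 2,
  gradFun = function(arr, labels) {
    g <- array(0, dim = dim(arr)); g[, 1, 1, 1] <- 1; g
  }, id = "pixel-switch")
  arr <- array(0.4, dim = c(4, shape))
  ds <- imageSet(arr, rep(1L, 4), c("lo", "hi"))
  budget <- perturbationBudget(p = Inf, zeta = 100,
                               referenceNorm = 0.3)
  # first pass defeats every image (pixel pushed above 0.5); later
  # passes must leave rho bitwise unchanged
  u1 <- generateUAP(cls, ds, budget, attackConfig(epsilon = 0.2, iMax = 1))
  u5 <- generateUAP(cls, ds, budget, attackConfig(epsilon = 0.2, iMax = 5))
  expect_identical(u1@rho, u5@rho)
})

test_that("compiled and reference UAP paths agree for the small CNN", {
  ds <- generateDataset(tinySpec(nClasses = 3, nTrain = 10, nTest = 3))
  net <- buildSmallCnn(c(16, 16, 1), nClasses = 3, seed = 2)
  budget <- perturbationBudget(p = 2, zeta = 6, dataset = ds$train)
  for (cfg in list(attackConfig(epsilon = 0.01, iMax = 2, seed = 3),
                   attackConfig(epsilon = 0.01, iMax = 2, seed = 3,
                                mode = "targeted", targetClass = 2L))) {
    fast <- generateUAP(net, ds$train, budget, cfg)
    slow <- selectMethod("generateUAP", "Classifier")(net, ds$train,
                                                      budget, cfg)
    expect_equal(fast@rho, slow@rho, tolerance = 1e-12)
  }
})

test_that("random UAPs sit on the norm sphere and are seeded", {
  shape <- c(8L, 8L, 1L)
  r1 <- sampleRandomUAP(shape, p = 2, xi = 0.5, seed = 1)
  expect_equal(lpNorm(r1@rho, 2), 0.5, tolerance = 1e-6)
  expect_identical(r1@rho, sampleRandomUAP(shape, p = 2, xi = 0.5,
                                           seed = 1)@rho)

  rinf <- sampleRandomUAP(shape, p = Inf, xi = 0.2, seed = 2)
  expect_true(all(abs(rinf@rho) == 0.2))

  rzero <- sampleRandomUAP(shape, p = 2, xi = 0, seed = 3)
  expect_true(all(rzero@rho == 0))

  # isotropy: per-component mean of many draws is near zero
  draws <- sapply(1:200, function(s)
    as.vector(sampleRandomUAP(c(2L, 2L, 1L), p = 2, xi = 1, seed = s)@rho))
  m <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(200)
  expect_true(all(abs(m) < 3 * se + 1e-12))
})

test_that("UAPs round trip through the text serialization", {
  ds <- generateDataset(tinySpec(nClasses = 2, nTrain = 6, nTest = 2))
  net <- buildSmallCnn(c(16, 16, 1), nClasses = 2, seed = 1)
  budget <- perturbationBudget(p = Inf, zeta = 3, dataset = ds$train)
  uap <- generateUAP(net, ds$train, budget,
                     attackConfig(epsilon = 0.01, iMax = 1, seed = 4))
  path <- tempfile("uap-")
  saveUAP(uap, path)
  back <- loadUAP(path)
  expect_equal(back@rho, uap@rho)
  expect_equal(back@budget@xi, uap@budget@xi)
  expect_identical(back@config@mode, uap@config@mode)
  file.remove(paste0(path, c(".csv", ".json")))
})
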
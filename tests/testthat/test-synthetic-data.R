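test_that("per-class counts follow proportional allocation and sum to n", {
  # the imbalanced 7-class composition: exact integer proportions
  spec <- syntheticTaskSpec(nClasses = 7,
                            classProportions = c(778, 4689, 370, 229,
                                                 764, 76, 94),
                            imageHeight = 8, imageWidth = 8,
                            nTrain = 7000, nTest = 70, seed = 1)
  counts <- uapkit:::allocateCounts(spec@nTrain, spec@classProportions)
  expect_identical(counts, as.integer(c(778, 4689, 370, 229, 764, 76, 94)))

  # balanced split
  expect_identical(uapkit:::allocateCounts(400, rep(1, 4)),
                   rep(100L, 4))

  # remainder goes to the largest class; totals always match
  for (n in c(10, 97, 500)) {
    w <- c(3, 10, 1)
    cnt <- uapkit:::allocateCounts(n, w)
    expect_identical(sum(cnt), as.integer(n))
  }
})

test_that("generated datasets are seeded, in-domain and correctly labelled", {
  spec <- tinySpec(nClasses = 4, nTrain = 40, nTest = 12)
  ds1 <- generateDataset(spec)
  ds2 <- generateDataset(spec)
  expect_identical(images(ds1$train), images(ds2$train))
  expect_identical(images(ds1$test), images(ds2$test))
  expect_identical(labels(ds1$train), labels(ds2$train))

  expect_true(all(images(ds1$train) >= 0 & images(ds1$train) <= 1))
  expect_identical(as.integer(table(labels(ds1$train))), rep(10L, 4))
  expect_identical(imageSplit(ds1$test), "test")

  # a different seed gives different pixels
  ds3 <- generateDataset(tinySpec(nClasses = 4, nTrain = 40, nTest = 12,
                                  seed = 99))
  expect_false(identical(images(ds1$train), images(ds3$train)))
})

test_that("all three pattern families produce valid RGB and gray sets", {
  for (fam in c("blob", "stripe", "texture")) {
    for (ch in c(1L, 3L)) {
      ds <- generateDataset(tinySpec(nClasses = 3, channels = ch,
                                     nTrain = 6, nTest = 3, family = fam))
      expect_identical(dim(images(ds$train)), c(6L, 16L, 16L, ch))
      expect_true(validObject(ds$train))
    }
  }
})

test_that("averageImageNorm matches definitions and a brute-force oracle", {
  # two 1-pixel images with values 0.5 and 1.0, p = Inf -> 0.75
  one <- imageSet(array(c(0.5, 1.0), dim = c(2, 1, 1, 1)), c(1L, 2L),
                  c("a", "b"))
  expect_equal(averageImageNorm(one, Inf), 0.75)

  # all-zero images -> 0 for both norms
  zero <- imageSet(array(0, dim = c(3, 2, 2, 1)), rep(1L, 3), "a")
  expect_equal(averageImageNorm(zero, 2), 0)
  expect_equal(averageImageNorm(zero, Inf), 0)

  # brute-force loop oracle on a 100-image seeded set
  ds <- generateDataset(tinySpec(nClasses = 4, nTrain = 100, nTest = 4))
  arr <- images(ds$train)
  oracle <- mean(sapply(seq_len(100), function(i)
    sqrt(sum(arr[i, , , ]^2))))
  expect_equal(averageImageNorm(ds$train, 2), oracle)
})

test_that("averageImageNorm is homogeneous under pixel scaling", {
  ds <- generateDataset(tinySpec(nClasses = 3, nTrain = 12, nTest = 3))
  for (p in list(2, Inf)) {
    base <- averageImageNorm(ds$train, p)
    for (c in c(0.25, 0.5)) {
      scaled <- ds$train
      scaled@images <- images(ds$train) * c
      expect_equal(averageImageNorm(scaled, p), c * base)
    }
  }
})

test_that("PNG folder round trip preserves labels and quantized pixels", {
  ds <- generateDataset(tinySpec(nClasses = 2, nTrain = 10, nTest = 2))
  dir <- tempfile("imgset-")
  saveImageFolder(ds$train, dir)
  back <- loadImageFolder(dir, channels = 1L)

  # class folders are read in lexicographic order
  expect_identical(classNames(back), sort(classNames(ds$train),
                                          method = "radix"))
  expect_identical(dim(images(back)), dim(images(ds$train)))

  # match images by class + stable filename ordering: labels preserved
  expect_identical(as.integer(table(labels(back))),
                   as.integer(table(labels(ds$train))))

  # pixels within 8-bit quantization
  ordOrig <- order(labels(ds$train))
  maxdev <- max(abs(sort(as.vector(images(back))) -
                    sort(as.vector(images(ds$train)))))
  expect_lt(maxdev, 1 / 255 + 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("RGB image sets round trip through PNG folders", {
  ds <- generateDataset(tinySpec(nClasses = 2, channels = 3L,
                                 nTrain = 4, nTest = 2))
  dir <- tempfile("imgset-rgb-")
  saveImageFolder(ds$train, dir)
  back <- loadImageFolder(dir)
  expect_identical(dim(images(back))[4], 3L)
  unlink(dir, recursive = TRUE)
})

test_that("folder loading rejects broken layouts", {
  dir <- tempfile("bad-")
  dir.create(file.path(dir, "empty_class"), recursive = TRUE)
  expect_error(loadImageFolder(dir), "empty class directory")

  bad <- file.path(dir, "classA")
  dir.create(bad)
  writeLines("not a png", file.path(bad, "junk.png"))
  expect_error(loadImageFolder(dir), "unreadable PNG")
  unlink(dir, recursive = TRUE)
})

test_that("resizing remaps pixels without leaving the domain", {
  ds <- generateDataset(tinySpec(nClasses = 2, nTrain = 4, nTest = 2))
  up <- resizeImages(ds$train, 32, 24)
  expect_identical(dim(images(up)), c(4L, 32L, 24L, 1L))
  expect_identical(labels(up), labels(ds$train))
  # nearest-neighbour: no new pixel values are invented
  expect_true(all(images(up) %in% images(ds$train)))
  # identity resize is exact
  same <- resizeImages(ds$train, 16, 16)
  expect_identical(images(same), images(ds$train))
})

test_that("task specs round trip through YAML", {
  spec <- tinySpec(nClasses = 3, nTrain = 9, nTest = 3, seed = 12)
  f <- tempfile(fileext = ".yaml")
  writeTaskSpec(spec, f)
  back <- readTaskSpec(f)
  expect_equal(back, spec)
  # datasets generated from the round-tripped spec are identical
  expect_identical(images(generateDataset(back)$train),
                   images(generateDataset(spec)$train))
  file.remove(f)
})

test_that("spec validity rejects malformed tasks", {
  expect_error(syntheticTaskSpec(nClasses = 1), "nClasses")
  expect_error(syntheticTaskSpec(nClasses = 3,
                                 classProportions = c(1, 2)),
               "classProportions")
  expect_error(syntheticTaskSpec(imageHeight = 0), "positive")
  expect_error(syntheticTaskSpec(nTrain = 2, nClasses = 4), "nTrain")
})
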
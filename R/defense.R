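#' @include AllClasses.R AllGenerics.R utils.R constructors.R attack.R evaluation.R
NULL

# Build the retraining set: a uniformly random ceiling(N/2) of the images
# kept clean, each remaining image perturbed by one of the supplied UAPs
# chosen uniformly at random, then clipped to [0, 1]. Labels stay the
# true labels.
modifiedTrainingSet <- function(trainSet, uaps) {
  arr <- images(trainSet)
  n <- dim(arr)[1]
  cleanIdx <- sample.int(n, ceiling(n / 2))
  perturbIdx <- setdiff(seq_len(n), cleanIdx)
  pick <- sample.int(length(uaps), length(perturbIdx), replace = TRUE)
  for (j in seq_along(perturbIdx)) {
    i <- perturbIdx[j]
    img <- arr[i, , , , drop = FALSE]
    dim(img) <- dim(arr)[2:4]
    arr[i, , , ] <- clip01(img + asRho(uaps[[pick[j]]]))
  }
  out <- trainSet
  out@images <- arr
  out
}

evalAttackMetric <- function(model, testSet, uap, config) {
  if (config@mode == "targeted")
    successRate(model, testSet, uap, config@targetClass)
  else foolingRate(model, testSet, uap)
}

#' Adversarial retraining defense
#'
#' Hardens a trained model against universal perturbations by iterating
#' five steps per round: (1) generate `nUaps` UAPs (independent seeds)
#' against the current model on the clean training images; (2) build a
#' modified training set — a random half kept clean, each remaining
#' image perturbed by one of those UAPs chosen at random; (3) fine-tune
#' the model for `ftEpochs` epochs on it; (4) generate one fresh UAP
#' against the just fine-tuned model; (5) record that UAP's fooling rate
#' (nontargeted) or targeted success rate on the test set, together with
#' the clean test accuracy.
#'
#' @param handle a trained classifier.
#' @param trainSet,testSet [ImageSet-class] splits.
#' @param budget the shared [perturbationBudget()] for all UAPs.
#' @param attack the [attackConfig()] describing the attack being
#'   defended against; its mode decides the recorded metric. The
#'   evaluation UAP of step (4) always uses this config.
#' @param baseTrain a [trainConfig()] supplying the fine-tuning recipe
#'   (momentum, batch size, augmentation); its epoch count is replaced
#'   by `ftEpochs` and its schedule by the constant `ftLearningRate`.
#' @param nUaps number of generation UAPs per round (default 10).
#' @param ftEpochs fine-tuning epochs per round (default 5).
#' @param rounds number of rounds (default 5); `rounds = 0` degrades to
#'   a plain evaluation of the undefended model.
#' @param ftLearningRate fine-tuning rate; defaults to the smallest rate
#'   in `baseTrain`'s schedule.
#' @param genAttack optional [attackConfig()] for the step-(1)
#'   generation UAPs (e.g. fewer passes for speed); defaults to `attack`.
#' @param genSubset optional number of training images each generation
#'   UAP is optimized on (a fresh random subset per UAP); default all.
#' @param evalSubset optional number of training images the step-(4)
#'   evaluation UAP is optimized on; default all.
#' @param seed integer seed driving all per-round randomness.
#' @return a list with `model` (the final fine-tuned classifier),
#'   `history` (a data.frame with one row per round: `round`, `metric`,
#'   `value`, `baseline`, `cleanTestAccuracy`), and `initial` (the same
#'   quantities for the undefended model, as round 0).
#' @export
adversarialRetrain <- function(handle, trainSet, testSet, budget, attack,
                               baseTrain = trainConfig(),
                               nUaps = 10L, ftEpochs = 5L, rounds = 5L,
                               ftLearningRate = NULL,
                               genAttack = attack, genSubset = NULL,
                               evalSubset = NULL, seed = 1L) {
  if (rounds < 0L) stop("rounds must be >= 0")
  if (is(handle, "SmallCNN") && !handle@trained)
    warning("retraining an untrained model")
  if (is.null(ftLearningRate))
    ftLearningRate <- min(baseTrain@lrSchedule$lr)
  metric <- if (attack@mode == "targeted") "success_rate" else "fooling_rate"
  nTrain <- nImages(trainSet)

  subSeeds <- withSeed(seed,
    matrix(sample.int(2147483646L, (rounds + 1L) * (nUaps + 3L)),
           nrow = rounds + 1L))

  genOne <- function(model, sd) {
    cfg <- genAttack
    cfg@seed <- as.integer(sd)
    X <- if (!is.null(genSubset) && genSubset < nTrain)
      trainSet[withSeed(sd, sample.int(nTrain, genSubset))] else trainSet
    generateUAP(model, X, budget, cfg)
  }
  evalOne <- function(model, sd) {
    cfg <- attack
    cfg@seed <- as.integer(sd)
    X <- if (!is.null(evalSubset) && evalSubset < nTrain)
      trainSet[withSeed(sd + 1L, sample.int(nTrain, evalSubset))]
    else trainSet
    uap <- generateUAP(model, X, budget, cfg)
    rpt <- evalAttackMetric(model, testSet, uap, attack)
    list(value = rpt@value, baseline = rpt@baseline,
         acc = accuracy(model, testSet))
  }

  initial <- evalOne(handle, subSeeds[1L, 1L])
  history <- data.frame(round = integer(0), metric = character(0),
                        value = numeric(0), baseline = numeric(0),
                        cleanTestAccuracy = numeric(0))
  model <- handle
  if (rounds >= 1L) {
    for (r in seq_len(rounds)) {
      rowSeeds <- subSeeds[r + 1L, ]
      uaps <- lapply(seq_len(nUaps),
                     function(j) genOne(model, rowSeeds[j]))
      modified <- withSeed(rowSeeds[nUaps + 1L],
                           modifiedTrainingSet(trainSet, uaps))
      ftConfig <- baseTrain
      ftConfig@epochs <- as.integer(ftEpochs)
      ftConfig@lrSchedule <- data.frame(untilEpoch = Inf,
                                        lr = ftLearningRate)
      ftConfig@seed <- as.integer(rowSeeds[nUaps + 2L])
      model <- trainClassifier(model, modified, ftConfig)
      ev <- evalOne(model, rowSeeds[nUaps + 3L])
      history <- rbind(history, data.frame(
        round = r, metric = metric, value = ev$value,
        baseline = if (is.na(ev$baseline)) NA_real_ else ev$baseline,
        cleanTestAccuracy = ev$acc))
    }
  }
  list(model = model, history = history,
       initial = data.frame(round = 0L, metric = metric,
                            value = initial$value,
                            baseline = if (is.na(initial$baseline))
                              NA_real_ else initial$baseline,
                            cleanTestAccuracy = initial$acc))
}
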
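#' @include AllClasses.R AllGenerics.R utils.R constructors.R synthetic-data.R classifier.R attack.R evaluation.R defense.R
NULL

#' Ready-made experiment configurations mirroring the three task shapes
#'
#' Returns a complete experiment configuration whose synthetic task
#' reproduces the class structure of one of the three reference medical
#' imaging tasks, scaled by `scale`:
#' \describe{
#'   \item{skin7}{7 classes, RGB, imbalanced with train proportions
#'     778/4689/370/229/764/76/94 per 7000 (test 3015), oversampling on.}
#'   \item{oct4}{4 classes, grayscale, balanced, 1960 train / 840 test
#'     per class.}
#'   \item{xray2}{2 classes, grayscale, balanced, 900 train / 270 test
#'     per class.}
#' }
#' Images are 64 x 64 blob-family patterns by default (the size is a
#' config knob, not a property of the task structure).
#'
#' @param name `"skin7"`, `"oct4"` or `"xray2"`.
#' @param scale positive multiplier on the split sizes.
#' @param imageSize image height/width in pixels (multiple of 8).
#' @param seed global experiment seed.
#' @return an experiment config list (see [runExperiment()]).
#' @examples
#' cfg <- makeFixture("oct4", scale = 1 / 10)
#' cfg$task@nTrain  # 784 = 196 per class
#' @export
makeFixture <- function(name = c("skin7", "oct4", "xray2"), scale = 1,
                        imageSize = 64L, seed = 1L) {
  name <- match.arg(name)
  stopifnot(scale > 0)
  base <- switch(name,
    skin7 = list(k = 7L, prop = c(778, 4689, 370, 229, 764, 76, 94),
                 channels = 3L, nTrain = 7000, nTest = 3015,
                 names = c("MEL", "NV", "BCC", "AKIEC", "BKL", "DF", "VASC"),
                 oversample = TRUE),
    oct4 = list(k = 4L, prop = rep(1, 4), channels = 1L,
                nTrain = 4 * 1960, nTest = 4 * 840,
                names = c("CNV", "DME", "DRUSEN", "NM"),
                oversample = FALSE),
    xray2 = list(k = 2L, prop = rep(1, 2), channels = 1L,
                 nTrain = 2 * 900, nTest = 2 * 270,
                 names = c("NORMAL", "PNEUMONIA"), oversample = FALSE))
  task <- syntheticTaskSpec(
    nClasses = base$k, classProportions = base$prop,
    imageHeight = imageSize, imageWidth = imageSize,
    channels = base$channels, patternFamily = "blob", noiseSd = 0.1,
    nTrain = max(base$k, round(base$nTrain * scale)),
    nTest = max(base$k, round(base$nTest * scale)),
    classNames = base$names, seed = seed)
  list(name = name, task = task,
       train = trainConfig(epochs = 10L, oversample = base$oversample,
                           lrSchedule = data.frame(untilEpoch = c(8, Inf),
                                                   lr = c(0.01, 0.003)),
                           seed = seed + 1L),
       budgets = list(list(p = 2, zeta = 8)),
       attack = attackConfig(seed = seed + 2L),
       defense = list(rounds = 5L, nUaps = 10L, ftEpochs = 5L,
                      ftLearningRate = 1e-3),
       stages = c("simulate", "train", "attack", "evaluate"),
       seed = seed)
}

md5OrNA <- function(path) {
  h <- tools::md5sum(path)
  unname(ifelse(is.na(h), NA_character_, h))
}

#' Run a configured end-to-end experiment
#'
#' Executes the requested stages in order — `simulate` (draw the
#' synthetic dataset), `train` (fit the small CNN), `attack` (generate
#' an optimized UAP and a matched random control per requested budget),
#' `evaluate` (fooling or success rates plus confusion matrices on the
#' test split), `sweep` (an R_f-versus-zeta table for UAPs and random
#' controls), `defend` (adversarial retraining) — and writes every
#' artifact under `outDir` together with a JSON manifest recording
#' files, md5 hashes and the seeds that produced them. Identical config
#' and seed reproduce an identical manifest apart from the timestamp.
#'
#' @param config a config list as produced by [makeFixture()]; relevant
#'   elements: `task`, `train`, `attack`, `budgets` (list of
#'   `list(p, zeta)`), `sweepZetas`, `defense`, `stages`, `seed`.
#' @param outDir output directory.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
runExperiment <- function(config, outDir = tempfile("uapkit-run-")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(seed = config$seed, stages = stages,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   artifacts = list())
  addArtifact <- function(name, file, seed = NULL) {
    manifest$artifacts[[name]] <<- list(
      file = basename(file), md5 = md5OrNA(file),
      seed = if (is.null(seed)) NA else seed)
  }
  stage <- "simulate"
  res <- tryCatch({
    ds <- NULL; model <- NULL
    if ("simulate" %in% stages) {
      ds <- generateDataset(config$task)
      f <- file.path(outDir, "dataset_summary.csv")
      utils::write.csv(data.frame(
        split = c("train", "test"),
        n = c(nImages(ds$train), nImages(ds$test)),
        classes = length(classNames(ds$train))), f, row.names = FALSE)
      addArtifact("dataset", f, config$task@seed)
    }
    if ("train" %in% stages) {
      stage <- "train"
      shape <- dim(images(ds$train))[2:4]
      model <- buildSmallCnn(shape, config$task@nClasses,
                             seed = config$seed + 10L)
      model <- trainClassifier(model, ds$train, config$train)
      f <- file.path(outDir, "model_accuracy.csv")
      utils::write.csv(data.frame(
        split = c("train", "test"),
        accuracy = c(accuracy(model, ds$train),
                     accuracy(model, ds$test))), f, row.names = FALSE)
      addArtifact("model", f, config$train@seed)
      fl <- file.path(outDir, "train_log.csv")
      utils::write.csv(trainingLog(model), fl, row.names = FALSE)
      addArtifact("train_log", fl, config$train@seed)
    }
    uaps <- list()
    if ("attack" %in% stages) {
      stage <- "attack"
      for (b in config$budgets) {
        budget <- perturbationBudget(p = b$p, zeta = b$zeta,
                                     dataset = ds$train)
        key <- sprintf("p%s_zeta%g", format(b$p), b$zeta)
        uap <- generateUAP(model, ds$train, budget, config$attack)
        f <- file.path(outDir, paste0("uap_", key))
        saveUAP(uap, f)
        addArtifact(paste0("uap_", key), paste0(f, ".json"),
                    config$attack@seed)
        rnd <- sampleRandomUAP(dim(uap@rho), budget = budget,
                               seed = config$seed + 20L)
        uaps[[key]] <- list(uap = uap, random = rnd, budget = budget)
      }
    }
    if ("evaluate" %in% stages) {
      stage <- "evaluate"
      rows <- list()
      for (key in names(uaps)) {
        for (type in c("uap", "random")) {
          rpt <- if (config$attack@mode == "targeted")
            successRate(model, ds$test, uaps[[key]][[type]],
                        config$attack@targetClass)
          else foolingRate(model, ds$test, uaps[[key]][[type]])
          rows[[paste(key, type)]] <- data.frame(
            budget = key, control = type, metric = rpt@metric,
            value = rpt@value,
            baseline = if (is.na(rpt@baseline)) NA_real_ else rpt@baseline)
          utils::write.csv(as.data.frame(rpt@confusion),
                          file.path(outDir, sprintf("confusion_%s_%s.csv",
                                                    key, type)))
        }
      }
      f <- file.path(outDir, "evaluation.csv")
      utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
      addArtifact("evaluation", f)
    }
    if ("sweep" %in% stages) {
      stage <- "sweep"
      zetas <- config$sweepZetas %||% c(0, 2, 4, 8)
      rows <- list()
      for (z in zetas) {
        budget <- perturbationBudget(p = config$budgets[[1]]$p, zeta = z,
                                     dataset = ds$train)
        uap <- generateUAP(model, ds$train, budget, config$attack)
        rnd <- sampleRandomUAP(dim(uap@rho), budget = budget,
                               seed = config$seed + 30L)
        rows[[as.character(z)]] <- data.frame(
          zeta = z,
          uap_rf = foolingRate(model, ds$test, uap)@value,
          random_rf = foolingRate(model, ds$test, rnd)@value)
      }
      f <- file.path(outDir, "sweep.csv")
      utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
      addArtifact("sweep", f, config$attack@seed)
    }
    if ("defend" %in% stages) {
      stage <- "defend"
      d <- config$defense
      budget <- perturbationBudget(p = config$budgets[[1]]$p,
                                   zeta = config$budgets[[1]]$zeta,
                                   dataset = ds$train)
      def <- adversarialRetrain(model, ds$train, ds$test, budget,
                                config$attack, baseTrain = config$train,
                                nUaps = d$nUaps, ftEpochs = d$ftEpochs,
                                rounds = d$rounds,
                                ftLearningRate = d$ftLearningRate,
                                genAttack = d$genAttack %||% config$attack,
                                genSubset = d$genSubset,
                                evalSubset = d$evalSubset,
                                seed = config$seed + 40L)
      f <- file.path(outDir, "defense_history.csv")
      utils::write.csv(rbind(def$initial, def$history), f,
                       row.names = FALSE)
      addArtifact("defense", f, config$seed + 40L)
    }
    manifest
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  jsonlite::write_json(res, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
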
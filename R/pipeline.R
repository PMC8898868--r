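## End-to-end pipeline: phantom dataset -> preprocessing -> two-stage liver
## segmentation -> lesion segmentation -> texture features and patches ->
## classifier training on a deterministic split -> held-out evaluation with
## exact binomial intervals and ROC/AUC.  Every stage keys its randomness off
## the one master seed, so a pipeline run is bit-reproducible.

#' Preprocess a slice: impulse removal then contrast enhancement
#'
#' Adaptive median filtering followed by histogram equalization at
#' \code{levels} gray levels, returned rescaled to [0, 1].
#'
#' @param image numeric matrix in [0, 1].
#' @param levels gray levels for equalization (default 256).
#' @param maxWindow adaptive median filter maximum window (default 7).
#' @return a numeric matrix in [0, 1].
#' @export
preprocessImage <- function(image, levels = 256L, maxWindow = 7L) {
  f <- adaptiveMedianFilter(image, maxWindow)
  histogramEqualize(f, levels) / (levels - 1L)
}

## score one phantom's segmented lesion mask; items without a detected
## lesion are scored 0, far below the default threshold (no lesion -> benign)
noLesionScore <- 0

#' Run the full pipeline on a synthetic dataset
#'
#' Generates \code{n} phantoms, preprocesses each slice, segments the liver
#' (coarse mask + SPF level set) and the lesions inside it, extracts one
#' standardized patch and texture feature vector per phantom (from the
#' largest detected lesion component), trains the convolutional scorer on a
#' seed-determined \code{trainFrac} split, and evaluates on the held-out
#' items.  Held-out phantoms with no detected lesion are called benign
#' directly.  When \code{outDir} is given, a byte-stable
#' \code{metrics.json} is written there (no timestamps, fixed digits).
#'
#' @param n dataset size.
#' @param seed master integer seed.
#' @param outDir optional output directory for metrics.json.
#' @param trainFrac training fraction (default 0.8).
#' @param liverParams,lesionParams [LevelSetParams-class] for the two stages.
#' @param config an [ICNNConfig-class]; its seed is derived from \code{seed}.
#' @param classBalance malignant fraction of the dataset.
#' @return a list: \code{metrics} (named list as written to JSON),
#'   \code{model}, \code{confusion}, \code{roc}.
#' @export
runPipeline <- function(n = 200L, seed = 1L, outDir = NULL, trainFrac = 0.8,
                        liverParams = levelSetParams(),
                        lesionParams = levelSetParams(epsilon = 0.05, sigmaG = 0.75,
                                                     maxIters = 200L),
                        config = icnnConfig(),
                        classBalance = 0.5) {
  phantoms <- makeDataset(n, classBalance = classBalance,
                          seed = deriveSeed(seed, 1L))
  liverDice <- numeric(n); lesionDice <- rep(NA_real_, n)
  items <- vector("list", n)
  truth <- vapply(phantoms, phantomLabel, character(1))
  for (i in seq_len(n)) {
    ph <- phantoms[[i]]
    ## the liver stage sees the fully preprocessed (equalized) slice, where
    ## global organ/background separation is easiest; the lesion stage,
    ## texture features and patches read the denoised slice, whose calibrated
    ## intensities keep the lesion-contrast signal equalization flattens
    amf <- adaptiveMedianFilter(phantomImage(ph))
    pre <- histogramEqualize(amf) / 255
    liver <- segmentLiver(pre, liverParams)
    lesions <- segmentLesions(amf, liver, lesionParams)
    liverDice[i] <- dice(liver, liverMask(ph))
    if (any(lesionMask(ph)) || any(lesions))
      lesionDice[i] <- dice(lesions, lesionMask(ph))
    if (any(lesions)) {
      main <- largestComponent(lesions)
      items[[i]] <- list(
        patch = makePatches(amf, main, config@patchSize)[[1L]],
        features = extractFeatureVector(amf, lesions),
        label = truth[i])
    }
  }

  nTrain <- round(n * trainFrac)
  ord <- withr::with_seed(deriveSeed(seed, 2L), sample(n))
  trainIdx <- ord[seq_len(nTrain)]
  testIdx <- ord[-seq_len(nTrain)]

  trainItems <- Filter(Negate(is.null), items[trainIdx])
  cfg <- config
  cfg@seed <- deriveSeed(seed, 3L)
  model <- trainICNN(trainItems, cfg)

  scores <- vapply(testIdx, function(i) {
    it <- items[[i]]
    if (is.null(it)) noLesionScore
    else scoreICNN(model, it$patch, it$features)
  }, numeric(1))
  preds <- predictLabel(scores, cfg@threshold)
  cm <- confusionCounts(truth[testIdx], preds)
  met <- classificationMetrics(cm)
  roc <- rocCurve(scores, truth[testIdx])

  nTest <- length(testIdx)
  ciAcc <- accuracyCI(cm@tp + cm@tn, nTest)
  ciSens <- accuracyCI(cm@tp, cm@tp + cm@fn)
  ciSpec <- accuracyCI(cm@tn, cm@tn + cm@fp)

  metrics <- list(
    n = n, nTrain = nTrain, nTest = nTest, seed = as.integer(seed),
    liverDiceMean = mean(liverDice),
    lesionDiceMean = mean(lesionDice, na.rm = TRUE),
    confusion = list(tp = cm@tp, fp = cm@fp, tn = cm@tn, fn = cm@fn),
    accuracy = unname(met["accuracy"]),
    sensitivity = unname(met["sensitivity"]),
    specificity = unname(met["specificity"]),
    ppv = unname(met["ppv"]),
    auc = aucValue(roc),
    accuracyCI95 = as.list(ciAcc),
    sensitivityCI95 = as.list(ciSens),
    specificityCI95 = as.list(ciSpec))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(metrics = metrics, model = model, confusion = cm, roc = roc)
}
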
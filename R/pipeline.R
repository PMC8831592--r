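## End-to-end orchestration: cohort -> parametric maps -> network inputs ->
## two-stage training (feature network frozen before the predictor is
## trained) -> patient-level predictions and metrics.

#' Parametric images for every plane of a cohort
#'
#' Simulates one reference-phantom frame matching the cohort geometry and
#' runs [generateMaps()] for every plane of every patient.
#'
#' @param cohort a [SyntheticCohort-class]
#' @param grid a [SlidingGrid-class]
#' @param config a [qusConfig()]
#' @param refSeed seed for the reference frame (derived from the cohort
#'   seed by default)
#' @return list (one element per patient) of lists of
#'   [ParametricImage-class].
#' @export
cohortParametricImages <- function(cohort, grid = SlidingGrid(),
                                   config = qusConfig(), refSeed = NULL) {
  if (is.null(refSeed)) refSeed <- cohort@seed + 1000003L
  g <- cohort@patients[[1]]@frames[[1]]@geometry
  pulse <- cohort@patients[[1]]@frames[[1]]@pulse
  ref <- simulateReferenceFrame(g, pulse, seed = refSeed)
  refCache <- new.env(parent = emptyenv())
  lapply(cohort@patients, function(pt)
    lapply(seq_along(pt@frames), function(i)
      generateMaps(pt@frames[[i]], ref, pt@contours[[i]], grid, config,
                   refCache = refCache)))
}

#' Train the full response-prediction model on a cohort
#'
#' Splits the cohort (stratified), derives training-set normalization
#' parameters, trains the feature network on single planes (plane label =
#' patient response), freezes it, extracts and averages plane features per
#' patient, trains the predictive network, and evaluates on the held-out
#' test patients.
#'
#' @param cohort a [SyntheticCohort-class]
#' @param mode "core" or "core+margin" network input mode
#' @param grid a [SlidingGrid-class] (used only when `images` is NULL)
#' @param qusCfg a [qusConfig()]
#' @param backbone a [backboneConfig()]
#' @param cfg a [trainConfig()] for the feature network
#' @param predictorCfg a [trainConfig()] for the predictive network; the
#'   default reuses `cfg` with a larger epoch budget (the fully connected
#'   stage takes far more, much cheaper, steps to converge at the same
#'   learning rate)
#' @param split optional precomputed [stratifiedSplit()] result
#' @param images optional precomputed [cohortParametricImages()] result,
#'   allowing several trainings (e.g. a label-permutation control) to share
#'   one expensive map computation
#' @param labels optional label override (e.g. permuted labels for a null
#'   control); defaults to the cohort's labels
#' @return object of class `qusResponseModel` with the trained networks,
#'   the split, per-patient features, test-set predictions and metrics.
#' @export
trainResponseModel <- function(cohort, mode = c("core+margin", "core"),
                               grid = SlidingGrid(), qusCfg = qusConfig(),
                               backbone = backboneConfig(),
                               cfg = trainConfig(), predictorCfg = NULL,
                               split = NULL, images = NULL, labels = NULL) {
  mode <- match.arg(mode)
  if (is.null(predictorCfg)) {
    predictorCfg <- cfg
    predictorCfg$maxEpochs <- max(cfg$maxEpochs, 400L)
    predictorCfg$patience <- max(cfg$patience, 40L)
  }
  if (is.null(labels)) labels <- unname(cohortLabels(cohort))
  labels <- assertLabels(labels)
  if (is.null(split)) split <- stratifiedSplit(labels, seed = cfg$seed)
  if (is.null(images))
    images <- cohortParametricImages(cohort, grid, qusCfg)

  trainImgs <- unlist(images[split$train], recursive = FALSE)
  normParams <- computeNormParams(trainImgs, mode = mode)
  # preprocess to full input size, then immediately reduce each plane to the
  # stem working resolution so the whole cohort stays small in memory
  inputs <- lapply(images, function(planes)
    lapply(planes, function(im)
      toWorkingRes(preprocessForNetwork(im, mode, normParams,
                                        size = backbone$inputSize),
                   backbone)))

  planeSet <- function(idx) {
    list(x = unlist(inputs[idx], recursive = FALSE),
         y = rep(labels[idx], vapply(inputs[idx], length, integer(1))))
  }
  tr <- planeSet(split$train)
  va <- planeSet(split$val)
  featureNet <- trainFeatureNet(tr$x, tr$y, va$x, va$y, backbone, cfg)

  featMat <- t(vapply(inputs, function(planes)
    averageFeatures(lapply(planes, function(x)
      nnForward(featureNet$backbone, x, train = FALSE))),
    numeric(backbone$featureDim)))
  rownames(featMat) <- vapply(cohort@patients, function(p) p@patientId,
                              character(1))
  predictor <- trainPredictor(featMat[split$train, , drop = FALSE],
                              labels[split$train],
                              featMat[split$val, , drop = FALSE],
                              labels[split$val], predictorCfg)
  testPred <- predictCohortFeatures(predictor,
                                    featMat[split$test, , drop = FALSE])
  metrics <- computeMetrics(testPred, labels[split$test])
  structure(list(featureNet = featureNet, predictor = predictor,
                 normParams = normParams, split = split, mode = mode,
                 features = featMat, labels = labels,
                 testPredictions = testPred, metrics = metrics),
            class = "qusResponseModel")
}

#' @export
print.qusResponseModel <- function(x, ...) {
  cat(sprintf(
    "qusResponseModel (%s, %s inputs): test accuracy %.2f, AUC %.2f\n",
    x$featureNet$config$architecture, x$mode, x$metrics$accuracy,
    x$metrics$auc))
  invisible(x)
}
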
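## Patient-level response prediction: plane feature vectors are averaged
## over the tumor volume and fed to a fully connected predictive network
## (256 -> 100 -> softmax(2), dropout after the first and second layer).

#' Average plane-level feature vectors for one patient
#'
#' Elementwise arithmetic mean over all imaging planes of a tumor;
#' invariant to plane ordering.
#'
#' @param planeVectors list of numeric 256-vectors, or a matrix with one
#'   plane per row
#' @param patientIds optional ids; mixing patients is an error
#' @return numeric vector (the averaged patient feature), with attributes
#'   `nPlanes` and (if supplied) `patientId`.
#' @export
averageFeatures <- function(planeVectors, patientIds = NULL) {
  if (is.matrix(planeVectors))
    planeVectors <- lapply(seq_len(nrow(planeVectors)),
                           function(i) planeVectors[i, ])
  if (length(planeVectors) == 0L) stop("no plane vectors supplied")
  if (!is.null(patientIds) && length(unique(patientIds)) > 1L)
    stop("plane vectors belong to different patients")
  len <- unique(vapply(planeVectors, length, integer(1)))
  if (length(len) != 1L) stop("plane vectors differ in length")
  out <- Reduce(`+`, planeVectors) / length(planeVectors)
  attr(out, "nPlanes") <- length(planeVectors)
  if (!is.null(patientIds)) attr(out, "patientId") <- patientIds[1]
  out
}

#' Train the patient-level predictive network
#'
#' Fully connected network on averaged 256-d patient features with a
#' 100-neuron hidden layer and a 2-class softmax output; dropout after the
#' first and second layer. Trained with class-weighted cross-entropy (same
#' cost weight C as the feature network), Adam, and early stopping on
#' validation loss. Deterministic given `cfg$seed`.
#'
#' @param features matrix (patients x 256) or list of numeric vectors
#' @param labels patient labels
#' @param valFeatures,valLabels optional validation patients
#' @param cfg a [trainConfig()]
#' @param hiddenWidth hidden-layer width
#' @return object of class `qusPredictor`.
#' @export
trainPredictor <- function(features, labels, valFeatures = NULL,
                           valLabels = NULL, cfg = trainConfig(),
                           hiddenWidth = 100) {
  toList <- function(f) {
    if (is.matrix(f)) lapply(seq_len(nrow(f)), function(i) f[i, ])
    else lapply(f, as.numeric)
  }
  xs <- toList(features)
  inputDim <- length(xs[[1]])
  withr::with_seed(cfg$seed, {
    net <- nnSeq(nnDropout(cfg$dropout), nnDense(inputDim, hiddenWidth),
                 nnRelu(), nnDropout(cfg$dropout), nnDense(hiddenWidth, 2))
    vxs <- if (is.null(valFeatures)) NULL else toList(valFeatures)
    fit <- trainNet(net, xs, labels, vxs, valLabels, cfg)
    structure(list(net = fit$node, inputDim = inputDim, cfg = cfg,
                   history = fit$history),
              class = "qusPredictor")
  })
}

#' Predict the response class of one patient
#'
#' Deterministic inference (dropout off): softmax probabilities over
#' (responder, non-responder) and the argmax label.
#'
#' @param predictor a `qusPredictor`
#' @param feature averaged patient feature vector
#' @param patientId identifier carried into the result
#' @return a [PredictionResult-class].
#' @export
predictPatient <- function(predictor, feature, patientId = "patient") {
  feature <- as.numeric(feature)
  if (length(feature) != predictor$inputDim)
    stop("feature length does not match the predictor input dimension")
  p <- softmaxVec(nnForward(predictor$net, feature, train = FALSE))
  new("PredictionResult", patientId = patientId, pResponder = p[1],
      pNonResponder = p[2],
      predictedLabel = responseLevels[which.max(p)])
}

#' Predict many patients into a data.frame
#'
#' @param predictor a `qusPredictor`
#' @param features matrix (patients x 256), rownames used as patient ids
#' @return data.frame(patientId, pResponder, pNonResponder, predictedLabel)
#' @export
predictCohortFeatures <- function(predictor, features) {
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(nrow(features)))
  res <- lapply(seq_len(nrow(features)), function(i)
    predictPatient(predictor, features[i, ], ids[i]))
  data.frame(patientId = ids,
             pResponder = vapply(res, function(r) r@pResponder, numeric(1)),
             pNonResponder = vapply(res, function(r) r@pNonResponder,
                                    numeric(1)),
             predictedLabel = vapply(res, function(r) r@predictedLabel,
                                     character(1)))
}

#' @export
print.qusPredictor <- function(x, ...) {
  cat(sprintf("qusPredictor: %d -> 100 -> 2 fully connected network%s\n",
              x$inputDim,
              if (is.null(x$history)) " (untrained)" else
                sprintf(", %d epochs", nrow(x$history))))
  invisible(x)
}
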
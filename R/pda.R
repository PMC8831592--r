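## Occlusion-based explanation: prediction difference analysis (PDA).
## A small patch of one input parametric image of one plane is zeroed, the
## patient-level probability of the originally predicted class is
## recomputed with the other planes' features fixed, and the absolute
## probability change is recorded at the patch center.

#' Prediction difference (occlusion) maps for one plane
#'
#' For each channel and each occluding-patch position (patch side
#' `patchSize` pixels, 50% overlap by default, so the patch advances by
#' patchSize/2), the patch in that single channel of the target plane is
#' set to zero, the target plane's features are re-extracted, the patient
#' feature average is rebuilt with the remaining planes' features held
#' fixed, and |delta p| of the originally predicted class is assigned to
#' the patch center. One map per channel (MBF, SI, ESD, EAC).
#'
#' @param featureNet a trained `qusFeatureNet`
#' @param predictor a trained `qusPredictor`
#' @param planes list of [NetworkInput-class] for the patient
#' @param targetPlane index of the occluded plane
#' @param patchSize occluding patch side (pixels)
#' @param overlap overlap fraction between adjacent patches
#' @return a [PdaMap-class]
#' @export
pdaMaps <- function(featureNet, predictor, planes, targetPlane = 1L,
                    patchSize = 8L, overlap = 0.5) {
  if (targetPlane < 1L || targetPlane > length(planes))
    stop("targetPlane must index one of the patient's planes")
  tens <- inputToArray(planes[[targetPlane]])
  H <- dim(tens)[1]
  if (patchSize > H) stop("patch larger than image")
  step <- max(1L, as.integer(round(patchSize * (1 - overlap))))
  starts <- seq(1L, H - patchSize + 1L, by = step)
  nPos <- length(starts)

  feats <- lapply(planes, function(p) extractFeatures(featureNet, p))
  base <- averageFeatures(feats)
  others <- if (length(feats) > 1L)
    Reduce(`+`, feats[-targetPlane]) else 0
  p0 <- softmaxVec(nnForward(predictor$net, as.numeric(base),
                             train = FALSE))
  cls <- which.max(p0)
  impact <- array(0, c(nPos, nPos, 4))
  for (ch in 1:4) {
    for (ir in seq_len(nPos)) {
      rows <- starts[ir]:(starts[ir] + patchSize - 1L)
      for (ic in seq_len(nPos)) {
        cols <- starts[ic]:(starts[ic] + patchSize - 1L)
        if (all(tens[rows, cols, ch] == 0)) next  # zero patch: no-op
        occ <- tens
        occ[rows, cols, ch] <- 0
        fOcc <- extractFeatures(featureNet, occ)
        avg <- (others + fOcc) / length(feats)
        p1 <- softmaxVec(nnForward(predictor$net, as.numeric(avg),
                                   train = FALSE))
        impact[ir, ic, ch] <- abs(p1[cls] - p0[cls])
      }
    }
  }
  new("PdaMap", impact = impact, patchSize = as.integer(patchSize),
      overlap = overlap, baseProbability = p0[cls],
      predictedLabel = responseLevels[cls])
}
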
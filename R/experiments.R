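## Desk-scale synthetic evaluation experiment: one call simulates a cohort
## with strong class separation, builds parametric maps, trains the
## two-stage model and reports held-out patient-level performance, with an
## optional label-permutation null control sharing the same maps.

#' Standard synthetic end-to-end experiment
#'
#' Simulates a cohort of `nPatients` patients (4--7 planes each, elliptical
#' cores with class-dependent microstructure, clinical class imbalance),
#' computes core+margin parametric maps with a 2 mm sliding window, trains
#' the feature network and patient-level predictor, and evaluates on the
#' stratified held-out test set. The desk-scale frame geometry
#' (~26 x 23 mm planes, 0.4 mm line pitch), 8--12 mm tumors, the 50%
#' window overlap and the short epoch budget keep a full run in the
#' low minutes on one CPU; all physical constants (pulse band, sampling,
#' reference phantom, cost weighting, dropout, learning rate) are the
#' package defaults.
#'
#' @param seed integer; governs the cohort, the split and all training
#'   randomness
#' @param nPatients cohort size
#' @param responderFraction class mix (default the clinical 76.2%)
#' @param architecture "ran" or "resnet" feature backbone
#' @param mode "core+margin" or "core" network inputs
#' @param overlap sliding-window overlap used for the maps
#' @param includeNull also train a label-permutation control on the same
#'   maps (permuted training and evaluation labels) and report its AUC
#' @param cfg optional [trainConfig()] override (seed is still taken from
#'   `seed`)
#' @return list with elements `auc`, `accuracy`, `metrics`, `model`, and
#'   (if requested) `nullAuc`.
#' @export
syntheticExperiment <- function(seed, nPatients = 60,
                                responderFraction = 0.762,
                                architecture = "ran",
                                mode = "core+margin", overlap = 0.5,
                                includeNull = FALSE, cfg = NULL) {
  geometry <- FrameGeometry(nLines = 64, nSamples = 1200,
                            lateralPitch = 0.4, depthOffset = 8)
  cohort <- simulateCohort(nPatients, responderFraction,
                           geometry = geometry,
                           tumorDiameterRange = c(8, 12), seed = seed)
  images <- cohortParametricImages(cohort, SlidingGrid(2, overlap))
  if (is.null(cfg)) cfg <- trainConfig(maxEpochs = 12, patience = 4)
  cfg$seed <- as.integer(seed)
  backbone <- backboneConfig(architecture, "small", inputSize = 512)
  model <- trainResponseModel(cohort, mode, backbone = backbone, cfg = cfg,
                              images = images)
  out <- list(auc = model$metrics$auc, accuracy = model$metrics$accuracy,
              metrics = model$metrics, model = model, cohort = cohort)
  if (includeNull) {
    labs <- unname(cohortLabels(cohort))
    permuted <- withr::with_seed(seed + 13L, sample(labs))
    nullModel <- trainResponseModel(cohort, mode, backbone = backbone,
                                    cfg = cfg, images = images,
                                    labels = permuted)
    out$nullAuc <- nullModel$metrics$auc
  }
  out
}

#' Single-window spectral parameter recovery experiment
#'
#' Simulates one large analysis window (many scan lines) of a homogeneous
#' medium plus a matched reference frame per seed, runs the full spectral
#' chain, and reports the relative ESD error and absolute EAC error (dB)
#' against the known truth.
#'
#' @param seeds integer vector, one replicate per seed
#' @param nLines scan lines per window (spectral averaging depth)
#' @param esd,eacDb ground-truth scattering parameters
#' @return data.frame(seed, esd, eac, esdRelErr, eacAbsErrDb)
#' @export
spectralRecoveryExperiment <- function(seeds, nLines = 2000, esd = 80,
                                       eacDb = 30) {
  g <- FrameGeometry(nLines = nLines, nSamples = 360, lateralPitch = 0.05,
                     depthOffset = 10)
  p <- AcousticPulse()
  cfg <- qusConfig()
  rows <- 100:203  # one 2 mm gate
  depth <- sampleDepthMm(g, mean(rows)) / 10
  res <- lapply(seeds, function(s) {
    fr <- simulateRFFrame(ScatteringSpec(esd, eacDb,
                                         attenuation = cfg$alphaSample),
                          g, p, seed = s)
    ref <- simulateReferenceFrame(g, p, seed = s + 5000L,
                                  attenuation = cfg$alphaRef)
    sW <- meanPowerSpectrum(rfSamples(fr)[rows, ],
                            p@samplingFrequency)
    rW <- meanPowerSpectrum(rfSamples(ref)[rows, ],
                            p@samplingFrequency)
    est <- estimateQus(sW, rW, depth, 1, cfg)
    data.frame(seed = s, esd = est@esd, eac = est@eac,
               esdRelErr = abs(est@esd - esd) / esd,
               eacAbsErrDb = abs(est@eac - eacDb))
  })
  do.call(rbind, res)
}
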
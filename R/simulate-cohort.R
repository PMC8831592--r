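## Multi-plane synthetic cohorts with known microstructure, labels and
## survival, mirroring the clinical acquisition structure: 4-7 scan planes
## per patient, an elliptical tumor core per plane, a 5 mm margin shell with
## intermediate scattering properties, and class-dependent exponential
## recurrence-free survival with independent uniform censoring.

#' Default class-dependent scattering parameters
#'
#' Responders and non-responders are given distinct core/margin
#' microstructure (ESD in um, EAC in dB). The magnitudes are free synthetic
#' parameters (tissue-scale scatterers with a strong class contrast); they
#' are not calibrated to clinical tissue.
#'
#' @export
cohortClassParams <- function() {
  list(
    responder = list(core = list(esd = 60, eacDb = 25),
                     margin = list(esd = 45, eacDb = 22)),
    `non-responder` = list(core = list(esd = 110, eacDb = 35),
                           margin = list(esd = 80, eacDb = 30)),
    background = list(esd = 30, eacDb = 20),
    attenuation = 1.0,
    soundSpeed = 1540)
}

#' Default survival-model parameters
#'
#' Exponential event times with a lower hazard for responders, censored
#' uniformly on [0, censorMaxMonths] (10-year follow-up).
#'
#' @export
cohortSurvivalParams <- function() {
  list(hazard = c(responder = 0.004, `non-responder` = 0.02),
       censorMaxMonths = 120)
}

#' Simulate right-censored survival records
#'
#' Exponential event times with rate `hazard` (per month), independently
#' censored by a uniform draw on [0, censorMax].
#'
#' @param n number of subjects
#' @param hazard events per month
#' @param censorMax months
#' @param group label attached to the records
#' @return data.frame(time, event, group); time > 0.
#' @export
simulateSurvivalRecords <- function(n, hazard, censorMax = 120,
                                    group = "group") {
  tEvent <- stats::rexp(n, rate = hazard)
  tCens <- stats::runif(n, 0, censorMax)
  data.frame(time = pmax(pmin(tEvent, tCens), 1e-6),
             event = tEvent <= tCens, group = group)
}

#' Elliptical tumor scattering field
#'
#' Ground-truth field function for an elliptical tumor core at
#' (`cx`, `cz`) mm with semi-axes (`ra`, `rb`): class-dependent core
#' parameters inside the ellipse, margin parameters within a `marginMm`
#' offset shell (axis-offset approximation), background outside. The
#' returned function maps (lateral positions, depth) to per-line ESD/EAC
#' and plugs into [simulateRFFrame()]'s `field` argument.
#'
#' @param cx,cz ellipse center (mm)
#' @param ra,rb semi-axes (mm)
#' @param params a [cohortClassParams()]-shaped list
#' @param label "responder" or "non-responder"
#' @param marginMm margin-shell thickness (mm)
#' @export
ellipseField <- function(cx, cz, ra, rb, params, label, marginMm = 5) {
  core <- params[[label]]$core
  marg <- params[[label]]$margin
  bg <- params$background
  function(lats, depth) {
    u <- ((lats - cx) / ra)^2 + ((depth - cz) / rb)^2
    v <- ((lats - cx) / (ra + marginMm))^2 + ((depth - cz) / (rb + marginMm))^2
    esd <- ifelse(u <= 1, core$esd, ifelse(v <= 1, marg$esd, bg$esd))
    eac <- ifelse(u <= 1, core$eacDb, ifelse(v <= 1, marg$eacDb, bg$eacDb))
    list(esd = esd, eacDb = eac)
  }
}

#' Elliptical contour polygon
#'
#' @param cx,cz center (mm)
#' @param ra,rb semi-axes (mm)
#' @param n number of vertices
#' @return n x 2 matrix of (lateral, axial) vertices.
#' @export
ellipsePolygon <- function(cx, cz, ra, rb, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + ra * cos(th), cz + rb * sin(th))
}

#' Simulate a multi-plane patient cohort
#'
#' Generates `nPatients` patients with stratified class labels (exact
#' largest-remainder counts), 4--7 RF scan planes each with an elliptical
#' tumor-core contour, class-dependent scattering inside the core and a
#' distinct 5 mm margin shell, and class-dependent exponential survival
#' with independent censoring. Fully reproducible from `seed`.
#'
#' @param nPatients >= 2
#' @param responderFraction strictly inside (0, 1); both classes must be
#'   represented after allocation
#' @param classParams see [cohortClassParams()]
#' @param survivalParams see [cohortSurvivalParams()]
#' @param geometry a [FrameGeometry-class]; the default is a 6 cm x 4 cm
#'   plane at 40 MHz sampling
#' @param pulse an [AcousticPulse-class]
#' @param tumorDiameterRange range (mm) the drawn tumor major diameter is
#'   truncated to; draws are N(52, 27) mm, the clinical initial-size
#'   distribution, truncated to fit the frame with its margin
#' @param seed integer
#' @param segmentLength axial synthesis segment (samples)
#' @return a [SyntheticCohort-class]
#' @export
simulateCohort <- function(nPatients, responderFraction = 0.762,
                           classParams = cohortClassParams(),
                           survivalParams = cohortSurvivalParams(),
                           geometry = NULL, pulse = AcousticPulse(),
                           tumorDiameterRange = c(15, 45),
                           seed = 1L, segmentLength = 128) {
  if (nPatients < 2) stop("nPatients must be >= 2")
  if (responderFraction <= 0 || responderFraction >= 1)
    stop("responderFraction must be strictly inside (0, 1)")
  if (is.null(geometry))
    geometry <- FrameGeometry(nLines = 256, nSamples = 2048,
                              lateralPitch = 60 / 256, depthOffset = 10,
                              soundSpeed = classParams$soundSpeed,
                              samplingFrequency = pulse@samplingFrequency)
  counts <- largestRemainder(c(responderFraction, 1 - responderFraction),
                             nPatients)
  if (any(counts == 0L))
    stop("both classes must be represented; adjust nPatients or fraction")
  labels <- rep(responseLevels, counts)

  latExtent <- geometry@nLines * geometry@lateralPitch
  axExtent <- geometry@nSamples * geometry@axialPitch
  marginMm <- 5

  withr::with_seed(seed, {
    labels <- sample(labels)
    pts <- vector("list", nPatients)
    for (i in seq_len(nPatients)) {
      lab <- labels[i]
      dia <- min(max(stats::rnorm(1, 52, 27), tumorDiameterRange[1]),
                 tumorDiameterRange[2])
      ra0 <- dia / 2
      rb0 <- ra0 * stats::runif(1, 0.6, 1)
      if (2 * (ra0 + marginMm) > latExtent ||
          2 * (rb0 + marginMm) > axExtent)
        stop("frame too small for the tumor diameter plus its margin")
      # center so the core plus margin stays inside the frame
      cx <- stats::runif(1, ra0 + marginMm, latExtent - ra0 - marginMm)
      cz <- stats::runif(1, geometry@depthOffset + rb0 + marginMm,
                         geometry@depthOffset + axExtent - rb0 - marginMm)
      nPlanes <- sample(4:7, 1)
      frames <- vector("list", nPlanes)
      contours <- vector("list", nPlanes)
      for (p in seq_len(nPlanes)) {
        ra <- ra0 * stats::runif(1, 0.9, 1.1)
        rb <- rb0 * stats::runif(1, 0.9, 1.1)
        fld <- ellipseField(cx, cz, ra, rb, classParams, lab, marginMm)
        planeSeed <- sample.int(.Machine$integer.max, 1)
        frames[[p]] <- simulateRFFrame(
          ScatteringSpec(esd = classParams[[lab]]$core$esd,
                         eacDb = classParams[[lab]]$core$eacDb,
                         attenuation = classParams$attenuation,
                         soundSpeed = classParams$soundSpeed),
          geometry, pulse, seed = planeSeed, segmentLength = segmentLength,
          field = fld)
        contours[[p]] <- RoiContour(ellipsePolygon(cx, cz, ra, rb),
                                    planeId = sprintf("p%03d_plane%d", i, p))
      }
      surv <- simulateSurvivalRecords(1, survivalParams$hazard[[lab]],
                                      survivalParams$censorMaxMonths, lab)
      pts[[i]] <- new("PatientRecord",
                      patientId = sprintf("p%03d", i), frames = frames,
                      contours = contours, label = lab,
                      survivalMonths = surv$time, event = surv$event)
    }
    new("SyntheticCohort", patients = pts, classParams = classParams,
        survivalParams = survivalParams, seed = as.integer(seed))
  })
}

#' Stratified class counts for a cohort size
#'
#' Largest-remainder allocation used by [simulateCohort()]: the exact
#' responder / non-responder counts for a cohort of `n` patients.
#'
#' @param n cohort size
#' @param responderFraction responder proportion
#' @return named integer vector c(responder, `non-responder`).
#' @export
responseCounts <- function(n, responderFraction = 0.762) {
  counts <- largestRemainder(c(responderFraction, 1 - responderFraction), n)
  stats::setNames(counts, responseLevels)
}
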
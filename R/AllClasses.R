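#' @import methods
NULL

## ---------------------------------------------------------------------------
## Acoustic primitives
## ---------------------------------------------------------------------------

#' Transmit pulse description
#'
#' Frequency-domain description of the imaging pulse: center frequency,
#' -6 dB band edges and RF sampling frequency, all in MHz. The default
#' corresponds to a linear-array probe transmitting at ~6 MHz with a
#' -6 dB bandwidth of 3--8 MHz, sampled at 40 MHz.
#'
#' @slot centerFrequency center frequency (MHz)
#' @slot bandLow,bandHigh -6 dB band edges (MHz)
#' @slot samplingFrequency RF sampling frequency (MHz)
#' @export
setClass("AcousticPulse",
  representation(centerFrequency = "numeric", bandLow = "numeric",
                 bandHigh = "numeric", samplingFrequency = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@bandLow < object@centerFrequency &&
          object@centerFrequency < object@bandHigh))
      msg <- c(msg, "need bandLow < centerFrequency < bandHigh")
    if (object@samplingFrequency < 2 * object@bandHigh)
      msg <- c(msg, "samplingFrequency violates Nyquist for bandHigh")
    if (object@bandLow <= 0) msg <- c(msg, "bandLow must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @param centerFrequency,bandLow,bandHigh,samplingFrequency see slots
#' @rdname AcousticPulse-class
#' @export
AcousticPulse <- function(centerFrequency = 6, bandLow = 3, bandHigh = 8,
                          samplingFrequency = 40) {
  new("AcousticPulse", centerFrequency = centerFrequency, bandLow = bandLow,
      bandHigh = bandHigh, samplingFrequency = samplingFrequency)
}

#' Scattering ground truth for a medium
#'
#' Effective scatterer diameter (ESD, micrometres), effective acoustic
#' concentration (EAC, dB re an arbitrary fixed reference), attenuation
#' (dB/MHz/cm) and sound speed (m/s).
#'
#' @slot esd effective scatterer diameter (um)
#' @slot eacDb 10*log10 acoustic concentration (dB)
#' @slot attenuation attenuation coefficient (dB/MHz/cm)
#' @slot soundSpeed speed of sound (m/s)
#' @export
setClass("ScatteringSpec",
  representation(esd = "numeric", eacDb = "numeric", attenuation = "numeric",
                 soundSpeed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@esd <= 0) msg <- c(msg, "esd must be > 0")
    if (object@attenuation < 0) msg <- c(msg, "attenuation must be >= 0")
    if (object@soundSpeed <= 0) msg <- c(msg, "soundSpeed must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param esd,eacDb,attenuation,soundSpeed see slots
#' @rdname ScatteringSpec-class
#' @export
ScatteringSpec <- function(esd, eacDb, attenuation = 1.0, soundSpeed = 1540) {
  new("ScatteringSpec", esd = esd, eacDb = eacDb, attenuation = attenuation,
      soundSpeed = soundSpeed)
}

#' Scan-plane geometry
#'
#' Pixel geometry of one RF frame. The axial pitch is derived from the sound
#' speed and sampling frequency as c/(2 f_s) and is not a free parameter.
#'
#' @slot nLines number of scan lines (lateral)
#' @slot nSamples samples per line (axial)
#' @slot lateralPitch lateral spacing (mm/line)
#' @slot axialPitch axial spacing (mm/sample), = c/(2 f_s)
#' @slot depthOffset depth of the first sample (mm)
#' @export
setClass("FrameGeometry",
  representation(nLines = "integer", nSamples = "integer",
                 lateralPitch = "numeric", axialPitch = "numeric",
                 depthOffset = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nLines < 1L || object@nSamples < 1L)
      msg <- c(msg, "nLines and nSamples must be positive")
    if (object@lateralPitch <= 0 || object@axialPitch <= 0)
      msg <- c(msg, "pitches must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @param nLines,nSamples,lateralPitch,depthOffset see slots
#' @param soundSpeed m/s, used with `samplingFrequency` to derive the axial pitch
#' @param samplingFrequency MHz
#' @rdname FrameGeometry-class
#' @export
FrameGeometry <- function(nLines, nSamples, lateralPitch,
                          depthOffset = 0, soundSpeed = 1540,
                          samplingFrequency = 40) {
  new("FrameGeometry", nLines = as.integer(nLines),
      nSamples = as.integer(nSamples), lateralPitch = lateralPitch,
      axialPitch = axialPitchMm(soundSpeed, samplingFrequency),
      depthOffset = depthOffset)
}

#' Radiofrequency frame
#'
#' Raw backscattered RF samples for one scan plane, stored axial-by-lateral
#' (rows = samples along depth, columns = scan lines), together with the
#' geometry, pulse and -- for simulated frames -- the ground-truth scattering
#' description (`truth`, a list; see [simulateRFFrame()]).
#'
#' @slot samples numeric matrix, nSamples x nLines
#' @slot geometry a [FrameGeometry-class]
#' @slot pulse an [AcousticPulse-class]
#' @slot truth list with ground-truth fields (possibly empty)
#' @export
setClass("RFFrame",
  representation(samples = "matrix", geometry = "FrameGeometry",
                 pulse = "AcousticPulse", truth = "list"),
  validity = function(object) {
    msg <- NULL
    if (!all(is.finite(object@samples))) msg <- c(msg, "non-finite samples")
    if (nrow(object@samples) != object@geometry@nSamples ||
        ncol(object@samples) != object@geometry@nLines)
      msg <- c(msg, "samples dimensions do not match geometry")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Spectral objects
## ---------------------------------------------------------------------------

#' Gated analysis window
#'
#' A rectangular block of RF data extracted for spectral analysis: rows are
#' gated axial samples, columns are scan lines.
#'
#' @slot segment numeric matrix (gated samples x lines)
#' @slot centerDepth depth of the gate center (cm)
#' @slot lateralExtent,axialExtent physical extents (mm)
#' @export
setClass("GatedWindow",
  representation(segment = "matrix", centerDepth = "numeric",
                 lateralExtent = "numeric", axialExtent = "numeric"),
  validity = function(object) {
    if (object@lateralExtent <= 0 || object@axialExtent <= 0)
      "extents must be positive" else TRUE
  })

#' @param segment,centerDepth,lateralExtent,axialExtent see slots
#' @rdname GatedWindow-class
#' @export
GatedWindow <- function(segment, centerDepth, lateralExtent, axialExtent) {
  new("GatedWindow", segment = as.matrix(segment), centerDepth = centerDepth,
      lateralExtent = lateralExtent, axialExtent = axialExtent)
}

#' Mean power spectrum of a gated window
#'
#' @slot freqs frequency grid (MHz), strictly increasing
#' @slot power linear-scale power, averaged over lines
#' @slot nLines number of scan lines averaged
#' @export
setClass("MeanPowerSpectrum",
  representation(freqs = "numeric", power = "numeric", nLines = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(object@power < 0)) msg <- c(msg, "power must be >= 0")
    if (length(object@freqs) != length(object@power))
      msg <- c(msg, "freqs/power length mismatch")
    if (is.unsorted(object@freqs, strictly = TRUE))
      msg <- c(msg, "freqs must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Reference-normalized spectrum in dB
#'
#' @slot freqs MHz, restricted to the analysis band
#' @slot values dB
#' @slot sampleAttenuation,refAttenuation dB/MHz/cm
#' @slot depth window-center depth (cm)
#' @export
setClass("NormalizedSpectrumDB",
  representation(freqs = "numeric", values = "numeric",
                 sampleAttenuation = "numeric", refAttenuation = "numeric",
                 depth = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@freqs) != length(object@values))
      msg <- c(msg, "freqs/values length mismatch")
    if (!all(is.finite(object@values))) msg <- c(msg, "non-finite values")
    if (is.null(msg)) TRUE else msg
  })

#' Backscatter coefficient estimate
#'
#' @slot freqs MHz
#' @slot bsc linear backscatter coefficient (fixed consistent internal unit)
#' @export
setClass("BscEstimate",
  representation(freqs = "numeric", bsc = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@freqs) != length(object@bsc))
      msg <- c(msg, "freqs/bsc length mismatch")
    if (any(object@bsc <= 0)) msg <- c(msg, "bsc must be > 0 on the band")
    if (is.null(msg)) TRUE else msg
  })

#' @param freqs,bsc see slots
#' @rdname BscEstimate-class
#' @export
BscEstimate <- function(freqs, bsc) new("BscEstimate", freqs = freqs, bsc = bsc)

#' Spectral parameter estimates for one window
#'
#' Mid-band fit (MBF, dB), spectral slope (SS, dB/MHz), 0-MHz intercept
#' (SI, dB), effective scatterer diameter (ESD, um) and effective acoustic
#' concentration (EAC, dB).
#'
#' @slot mbf,ss,si,esd,eac see description
#' @export
setClass("QusEstimate",
  representation(mbf = "numeric", ss = "numeric", si = "numeric",
                 esd = "numeric", eac = "numeric"),
  validity = function(object) {
    vals <- c(object@mbf, object@ss, object@si, object@esd, object@eac)
    if (!all(is.finite(vals))) "all parameters must be finite" else TRUE
  })

## ---------------------------------------------------------------------------
## Imaging / cohort objects
## ---------------------------------------------------------------------------

#' Tumor-core contour for one scan plane
#'
#' @slot planeId identifier
#' @slot polygon closed polygon, matrix of (lateral mm, axial mm) vertices
#' @export
setClass("RoiContour",
  representation(planeId = "character", polygon = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@polygon) < 3L) msg <- c(msg, "need >= 3 vertices")
    if (ncol(object@polygon) != 2L) msg <- c(msg, "polygon must be n x 2")
    if (abs(polygonArea(object@polygon)) <= 0)
      msg <- c(msg, "polygon must have positive area")
    if (is.null(msg)) TRUE else msg
  })

#' @param planeId,polygon see slots
#' @rdname RoiContour-class
#' @export
RoiContour <- function(polygon, planeId = "plane") {
  new("RoiContour", planeId = planeId, polygon = as.matrix(polygon))
}

#' Sliding-window analysis grid
#'
#' Square analysis windows of side `windowSize` mm advanced with a fixed
#' `overlapFraction` in both directions; the step is derived as
#' windowSize * (1 - overlap). The default (2 mm windows, 95% overlap)
#' gives 0.1 mm isotropic map pixels.
#'
#' @slot windowSize window side (mm)
#' @slot overlapFraction in [0, 1)
#' @slot step derived step (mm)
#' @export
setClass("SlidingGrid",
  representation(windowSize = "numeric", overlapFraction = "numeric",
                 step = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@overlapFraction < 0 || object@overlapFraction >= 1)
      msg <- c(msg, "overlapFraction must be in [0, 1)")
    if (object@step <= 0) msg <- c(msg, "step must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param windowSize,overlapFraction see slots
#' @rdname SlidingGrid-class
#' @export
SlidingGrid <- function(windowSize = 2, overlapFraction = 0.95) {
  new("SlidingGrid", windowSize = windowSize,
      overlapFraction = overlapFraction,
      step = windowSize * (1 - overlapFraction))
}

#' Multi-parametric QUS image for one scan plane
#'
#' Four co-registered parameter maps in fixed channel order
#' (MBF, SI, ESD, EAC) with binary masks for the tumor core and the
#' surrounding margin band.
#'
#' @slot channels numeric array height x width x 4, channel order MBF,SI,ESD,EAC
#' @slot coreMask,marginMask binary matrices, same height/width, disjoint
#' @slot pixelPitch mm per pixel (isotropic)
#' @export
setClass("ParametricImage",
  representation(channels = "array", coreMask = "matrix",
                 marginMask = "matrix", pixelPitch = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@channels)
    if (length(d) != 3L || d[3] != 4L)
      msg <- c(msg, "channels must be H x W x 4")
    if (!identical(dim(object@coreMask), d[1:2]) ||
        !identical(dim(object@marginMask), d[1:2]))
      msg <- c(msg, "mask dimensions must match channels")
    if (any(object@coreMask * object@marginMask != 0))
      msg <- c(msg, "core and margin masks must be disjoint")
    if (is.null(msg)) TRUE else msg
  })

#' @param channels,coreMask,marginMask,pixelPitch see slots
#' @rdname ParametricImage-class
#' @export
ParametricImage <- function(channels, coreMask, marginMask, pixelPitch) {
  new("ParametricImage", channels = channels,
      coreMask = coreMask * 1, marginMask = marginMask * 1,
      pixelPitch = pixelPitch)
}

#' Fixed-size normalized network input
#'
#' @slot tensor numeric array size x size x 4, values in [0, 1]
#' @slot mode "core" or "core+margin"
#' @export
setClass("NetworkInput",
  representation(tensor = "array", mode = "character"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@tensor)
    if (length(d) != 3L || d[1] != d[2] || d[3] != 4L)
      msg <- c(msg, "tensor must be square H x H x 4")
    if (min(object@tensor) < -1e-9 || max(object@tensor) > 1 + 1e-9)
      msg <- c(msg, "values must lie in [0, 1]")
    if (!object@mode %in% c("core", "core+margin"))
      msg <- c(msg, "mode must be 'core' or 'core+margin'")
    if (is.null(msg)) TRUE else msg
  })

#' @param tensor,mode see slots
#' @rdname NetworkInput-class
#' @export
NetworkInput <- function(tensor, mode = "core+margin") {
  new("NetworkInput", tensor = tensor, mode = mode)
}

#' One patient of a (synthetic) cohort
#'
#' @slot patientId identifier
#' @slot frames list of [RFFrame-class] scan planes (4--7)
#' @slot contours list of [RoiContour-class], one per plane
#' @slot label "responder" or "non-responder"
#' @slot survivalMonths recurrence-free time (months)
#' @slot event TRUE if recurrence/death observed, FALSE if censored
#' @export
setClass("PatientRecord",
  representation(patientId = "character", frames = "list", contours = "list",
                 label = "character", survivalMonths = "numeric",
                 event = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@label %in% c("responder", "non-responder"))
      msg <- c(msg, "label must be responder/non-responder")
    if (length(object@frames) != length(object@contours))
      msg <- c(msg, "frames/contours length mismatch")
    if (object@survivalMonths <= 0) msg <- c(msg, "survival time must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Synthetic patient cohort
#'
#' @slot patients list of [PatientRecord-class]
#' @slot classParams generator parameters actually used (list)
#' @slot survivalParams per-class hazards and censoring (list)
#' @slot seed integer seed the cohort was generated from
#' @export
setClass("SyntheticCohort",
  representation(patients = "list", classParams = "list",
                 survivalParams = "list", seed = "integer"),
  validity = function(object) {
    ok <- vapply(object@patients, is, logical(1), class2 = "PatientRecord")
    if (!all(ok)) "patients must be PatientRecord objects" else TRUE
  })

#' Patient-level prediction
#'
#' @slot patientId identifier
#' @slot pResponder,pNonResponder softmax probabilities (sum to 1)
#' @slot predictedLabel argmax label
#' @export
setClass("PredictionResult",
  representation(patientId = "character", pResponder = "numeric",
                 pNonResponder = "numeric", predictedLabel = "character"),
  validity = function(object) {
    msg <- NULL
    if (abs(object@pResponder + object@pNonResponder - 1) > 1e-6)
      msg <- c(msg, "probabilities must sum to 1")
    if (object@pResponder < 0 || object@pNonResponder < 0)
      msg <- c(msg, "probabilities must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Occlusion (prediction difference) maps
#'
#' Per-channel absolute prediction-change maps on the occluding-patch
#' center grid.
#'
#' @slot impact array nPos x nPos x 4, non-negative
#' @slot patchSize occluding patch side (pixels)
#' @slot overlap overlap fraction between adjacent patches
#' @slot baseProbability probability of the originally predicted class
#' @slot predictedLabel the class whose probability is tracked
#' @export
setClass("PdaMap",
  representation(impact = "array", patchSize = "integer", overlap = "numeric",
                 baseProbability = "numeric", predictedLabel = "character"),
  validity = function(object) {
    msg <- NULL
    if (any(object@impact < 0)) msg <- c(msg, "impact must be non-negative")
    d <- dim(object@impact)
    if (length(d) != 3L || d[3] != 4L) msg <- c(msg, "impact must be n x n x 4")
    if (is.null(msg)) TRUE else msg
  })
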
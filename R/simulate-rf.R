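## Synthetic RF generation.
##
## Frames are synthesized in the frequency domain: per scan line and per
## axial segment, white Gaussian noise is shaped by the square root of the
## expected power spectrum at the segment-center depth and transformed back.
## This gives an exact, testable spectral expectation
##   E[|DFT(x)|^2 / L] = |P(f)|^2 * BSC(f) * 10^(-4 alpha f d / 10)
## with P the pulse amplitude spectrum, BSC the backscatter-coefficient
## model, alpha in dB/MHz/cm and d the segment-center depth in cm (round-trip
## power attenuation, reference-phantom convention).

#' Pulse amplitude spectrum
#'
#' Two-sided Gaussian band-pass amplitude with its peak at the center
#' frequency and exactly half amplitude (-6 dB) at the band edges; the
#' left/right Gaussian widths are chosen so an asymmetric band such as
#' 3--8 MHz around 6 MHz is honored exactly. A smooth DC-kill factor
#' forces |P(0)| = 0 without perturbing the band (it deviates from 1 by
#' < 1e-15 above 2 MHz).
#'
#' @param pulse an [AcousticPulse-class]
#' @param freqGrid frequencies (MHz), must lie in [0, fs/2]
#' @return numeric vector |P(f)| with max 1 at the center frequency.
#' @export
makePulseSpectrum <- function(pulse, freqGrid) {
  fs2 <- pulse@samplingFrequency / 2
  if (any(freqGrid < 0 | freqGrid > fs2 + 1e-9))
    stop("freqGrid must lie within [0, Nyquist]")
  fc <- pulse@centerFrequency
  sigL <- (fc - pulse@bandLow) / sqrt(2 * log(2))
  sigR <- (pulse@bandHigh - fc) / sqrt(2 * log(2))
  sig <- ifelse(freqGrid <= fc, sigL, sigR)
  amp <- exp(-(freqGrid - fc)^2 / (2 * sig^2))
  amp * (1 - exp(-(freqGrid / 0.5)^2))
}

#' Spherical Gaussian form factor
#'
#' Frequency-dependent deviation from Rayleigh scattering for a Gaussian
#' impedance distribution of effective diameter `esd`:
#' F(f) = exp(-0.827 k^2 a^2), k = 2 pi f / c, a = esd/2. F(0) = 1.
#'
#' @param freqs MHz
#' @param esd effective scatterer diameter (um)
#' @param soundSpeed m/s
#' @export
gaussianFormFactor <- function(freqs, esd, soundSpeed = 1540) {
  a <- esd / 2 * 1e-6
  k <- 2 * pi * freqs * 1e6 / soundSpeed
  exp(-0.827 * k^2 * a^2)
}

#' Backscatter-coefficient model
#'
#' Spherical Gaussian form-factor model
#' BSC(f) = C0 * EAC_lin * a^6 k^4 exp(-0.827 k^2 a^2), with C0 = 1 in
#' internal units and EAC_lin = 10^(eacDb/10); EAC is therefore reported
#' relative to a fixed internal reference.
#'
#' @param freqs MHz
#' @param esd um
#' @param eacDb dB
#' @param soundSpeed m/s
#' @export
bscModel <- function(freqs, esd, eacDb, soundSpeed = 1540) {
  a <- esd / 2 * 1e-6
  k <- 2 * pi * freqs * 1e6 / soundSpeed
  10^(eacDb / 10) * a^6 * k^4 * exp(-0.827 * k^2 * a^2)
}

#' Expected segment power spectrum of a simulated frame
#'
#' @param freqs MHz
#' @param pulse [AcousticPulse-class]
#' @param spec [ScatteringSpec-class]
#' @param depthCm segment-center depth (cm)
#' @param bscFlat if non-NULL, a flat backscatter level used instead of the
#'   Gaussian form-factor model (reference-phantom mode)
#' @export
expectedPowerSpectrum <- function(freqs, pulse, spec, depthCm,
                                  bscFlat = NULL) {
  bsc <- if (is.null(bscFlat))
    bscModel(freqs, spec@esd, spec@eacDb, spec@soundSpeed)
  else rep(bscFlat, length(freqs))
  makePulseSpectrum(pulse, freqs)^2 * bsc *
    10^(-4 * spec@attenuation * freqs * depthCm / 10)
}

# synthesize one frame from a per-line/segment expected-spectrum rule.
# specAt(latsMm, depthMm) must return a list(esd=, eacDb=) of vectors over
# lines, or bscFlat gives a flat BSC. attenuation/soundSpeed are scalars.
#
# Segments of length L are synthesized independently at their center-depth
# attenuation and combined by overlap-add with a square-root periodic Hann
# cross-fade at L/4 hop (constant-overlap-add: the squared fades sum to 1),
# so the process is continuous in depth, analysis gates may straddle segment
# joins without boundary artifacts, and the piecewise-constant depth
# attenuation is sampled finely enough that point compensation at the
# window center stays accurate.
synthesizeFrame <- function(geometry, pulse, attenuation, soundSpeed,
                            specAt = NULL, bscFlat = NULL,
                            segmentLength = 128) {
  fs <- pulse@samplingFrequency
  nS <- geometry@nSamples; nL <- geometry@nLines
  lats <- lineLateralMm(geometry, seq_len(nL))
  samples <- matrix(0, nS, nL)
  L <- segmentLength
  hop <- L %/% 4
  w <- sqrt(0.25 * (1 - cos(2 * pi * (0:(L - 1)) / L)))
  kk <- 0:(L - 1)
  freqs <- pmin(kk, L - kk) * fs / L
  p2 <- makePulseSpectrum(pulse, freqs)^2
  fMid <- (pulse@bandLow + pulse@bandHigh) / 2
  for (s0 in seq(1 - (L - hop), nS, by = hop)) {
    s1 <- s0 + L - 1
    keep <- max(s0, 1):min(s1, nS)
    ctr <- min(max((s0 + s1) / 2, 1), nS)
    dCm <- sampleDepthMm(geometry, ctr) / 10
    attn <- 10^(-4 * attenuation * freqs * dCm / 10)
    # continuous within-segment level: amplitude ramp at the band-center
    # frequency relative to the segment-center depth
    dRowCm <- sampleDepthMm(geometry, s0:s1) / 10
    ramp <- 10^(-4 * attenuation * fMid * (dRowCm - dCm) / 20)
    noise <- matrix(stats::rnorm(L * nL), L, nL)
    seg <- if (is.null(specAt)) {
      S <- p2 * bscFlat * attn
      Re(stats::mvfft(stats::mvfft(noise) * sqrt(S), inverse = TRUE)) / L
    } else {
      fld <- specAt(lats, sampleDepthMm(geometry, ctr))
      key <- paste(fld$esd, fld$eacDb)
      out <- matrix(0, L, nL)
      for (u in unique(key)) {
        j <- which(key == u)
        S <- p2 * bscModel(freqs, fld$esd[j[1]], fld$eacDb[j[1]],
                           soundSpeed) * attn
        out[, j] <- Re(stats::mvfft(stats::mvfft(noise[, j, drop = FALSE]) *
                                      sqrt(S), inverse = TRUE)) / L
      }
      out
    }
    rel <- keep - s0 + 1
    samples[keep, ] <- samples[keep, ] +
      seg[rel, , drop = FALSE] * (w[rel] * ramp[rel])
  }
  samples
}

#' Simulate an RF frame
#'
#' Frequency-domain synthesis of a speckle frame whose across-line average
#' periodogram of any axial segment converges to the analytic expectation
#' (see [expectedPowerSpectrum()]). Attenuation is applied per axial
#' synthesis segment at the segment-center depth (piecewise constant).
#'
#' @param spec a [ScatteringSpec-class] (homogeneous medium); ignored fields
#'   are taken from `field` when that is supplied
#' @param geometry a [FrameGeometry-class]
#' @param pulse an [AcousticPulse-class]
#' @param seed integer seed; identical seeds give bit-identical frames
#' @param segmentLength axial synthesis segment (samples)
#' @param field optional function(latsMm, depthMm) returning
#'   list(esd=, eacDb=) vectors over the scan lines, for spatially varying
#'   media (attenuation and sound speed stay taken from `spec`)
#' @return an [RFFrame-class] with the ground truth attached in `truth`.
#' @export
simulateRFFrame <- function(spec, geometry, pulse = AcousticPulse(),
                            seed = 1L, segmentLength = 128, field = NULL) {
  stopifnot(is(spec, "ScatteringSpec"), is(geometry, "FrameGeometry"))
  samples <- withr::with_seed(seed, synthesizeFrame(
    geometry, pulse, spec@attenuation, spec@soundSpeed,
    specAt = if (is.null(field)) function(lats, depth)
      list(esd = rep(spec@esd, length(lats)),
           eacDb = rep(spec@eacDb, length(lats)))
    else field,
    segmentLength = segmentLength))
  truth <- list(spec = spec, field = field)
  new("RFFrame", samples = samples, geometry = geometry, pulse = pulse,
      truth = truth)
}

#' Simulate a reference-phantom frame
#'
#' A homogeneous calibration frame with the reference phantom's known
#' acoustics (attenuation 0.576 dB/MHz/cm, sound speed 1488 m/s) and a flat
#' backscatter coefficient `bscRef` stored with the frame. Used to cancel
#' the system transfer function in [normalizeSpectrum()].
#'
#' @param geometry a [FrameGeometry-class]
#' @param pulse an [AcousticPulse-class]
#' @param seed integer
#' @param bscRef flat backscatter level of the phantom (internal units)
#' @param attenuation,soundSpeed phantom acoustics; defaults are the
#'   calibrated values
#' @export
simulateReferenceFrame <- function(geometry, pulse = AcousticPulse(),
                                   seed = 1L, bscRef = 1,
                                   attenuation = 0.576, soundSpeed = 1488,
                                   segmentLength = 128) {
  samples <- withr::with_seed(seed, synthesizeFrame(
    geometry, pulse, attenuation, soundSpeed, bscFlat = bscRef,
    segmentLength = segmentLength))
  truth <- list(attenuation = attenuation, soundSpeed = soundSpeed,
                bscRef = bscRef, reference = TRUE)
  new("RFFrame", samples = samples, geometry = geometry, pulse = pulse,
      truth = truth)
}
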
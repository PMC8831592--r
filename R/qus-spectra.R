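## Spectral parameter estimation for one analysis window: Hanning-gated
## mean power spectra, reference-phantom normalization with attenuation
## compensation, linear band regression (Lizzi-Feleppa parameters) and
## spherical Gaussian form-factor inversion for ESD/EAC.

#' Analysis configuration
#'
#' Bundles the tunable estimation constants. The sample attenuation is a
#' configuration value (breast-tissue literature default, 1.0 dB/MHz/cm);
#' the reference attenuation defaults to the calibrated phantom value.
#'
#' @param alphaSample sample attenuation (dB/MHz/cm)
#' @param alphaRef reference-phantom attenuation (dB/MHz/cm)
#' @param soundSpeed sample sound speed (m/s), used for the wavenumber in
#'   the form-factor fit
#' @param band analysis band (MHz), the transducer's -6 dB bandwidth
#' @param esdGrid candidate effective scatterer diameters (um)
#' @param nfftFactor zero-padding factor: nfft is the next power of two
#'   >= nfftFactor * gated length
#' @return list of class `qusConfig`.
#' @export
qusConfig <- function(alphaSample = 1.0, alphaRef = 0.576, soundSpeed = 1540,
                      band = c(3, 8), esdGrid = seq(1, 300, by = 1),
                      nfftFactor = 4) {
  structure(list(alphaSample = alphaSample, alphaRef = alphaRef,
                 soundSpeed = soundSpeed, band = band, esdGrid = esdGrid,
                 nfftFactor = nfftFactor), class = "qusConfig")
}

#' Mean power spectrum of a gated window
#'
#' Hanning-gates every scan line of the window, zero-pads to `nfft` and
#' averages the squared DFT magnitudes across lines:
#' power[k] = mean_l |DFT(hanning * line_l)[k]|^2, reported on the
#' non-negative frequency half-grid.
#'
#' @param window a [GatedWindow-class] or a numeric matrix
#'   (gated samples x lines)
#' @param samplingFrequency MHz
#' @param nfft DFT length; default next power of two >= 4x gate length
#' @return a [MeanPowerSpectrum-class]
#' @export
meanPowerSpectrum <- function(window, samplingFrequency = 40, nfft = NULL) {
  seg <- if (is(window, "GatedWindow")) window@segment else as.matrix(window)
  n <- nrow(seg)
  if (n < 1L || ncol(seg) < 1L) stop("empty segment")
  if (is.null(nfft)) nfft <- nextPow2(4 * n)
  h <- hannWindow(n)
  padded <- matrix(0, nfft, ncol(seg))
  padded[seq_len(n), ] <- seg * h
  X <- stats::mvfft(padded)
  half <- seq_len(nfft %/% 2 + 1)
  power <- rowMeans(Mod(X[half, , drop = FALSE])^2)
  new("MeanPowerSpectrum",
      freqs = (half - 1) * samplingFrequency / nfft,
      power = power, nLines = ncol(seg))
}

#' Reference-phantom normalization
#'
#' Divides the sample spectrum by the reference spectrum (cancelling the
#' system transfer function and beam effects) and compensates the
#' attenuation mismatch at the window-center depth:
#' values(f) = 10 log10(S_s/S_r) + 4 (alpha_s - alpha_r) f d, restricted
#' to the analysis band. The 4 f d term is the round-trip power
#' compensation for attenuation coefficients quoted in dB/MHz/cm.
#'
#' @param sample,reference [MeanPowerSpectrum-class] on identical grids
#' @param alphaSample,alphaRef dB/MHz/cm
#' @param depthCm window-center depth (cm)
#' @param band analysis band (MHz)
#' @return a [NormalizedSpectrumDB-class]
#' @export
normalizeSpectrum <- function(sample, reference, alphaSample, alphaRef,
                              depthCm, band = c(3, 8)) {
  if (length(sample@freqs) != length(reference@freqs) ||
      any(abs(sample@freqs - reference@freqs) > 1e-9))
    stop("sample and reference must share the frequency grid")
  sel <- sample@freqs >= band[1] - 1e-9 & sample@freqs <= band[2] + 1e-9
  if (any(reference@power[sel] <= 0))
    stop("reference power must be positive on the analysis band")
  f <- sample@freqs[sel]
  vals <- 10 * log10(sample@power[sel] / reference@power[sel]) +
    4 * (alphaSample - alphaRef) * f * depthCm
  new("NormalizedSpectrumDB", freqs = f, values = vals,
      sampleAttenuation = alphaSample, refAttenuation = alphaRef,
      depth = depthCm)
}

# closed-form simple OLS; cross-checked against stats::lm in the tests
olsLine <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

#' Linear band regression (Lizzi-Feleppa parameters)
#'
#' Ordinary least squares of the normalized spectrum (dB) against frequency
#' (MHz) within the analysis band. Returns the spectral slope (SS), the
#' 0-MHz intercept (SI), and the mid-band fit (MBF) evaluated at the band
#' midpoint (5.5 MHz for a 3--8 MHz band).
#'
#' @param norm a [NormalizedSpectrumDB-class]
#' @param fMid evaluation frequency for MBF; default the band midpoint
#' @return list(ss, si, mbf)
#' @export
fitLinearBand <- function(norm, fMid = NULL) {
  f <- norm@freqs
  if (length(unique(f)) < 2L) stop("need >= 2 distinct frequencies")
  if (is.null(fMid)) fMid <- (min(f) + max(f)) / 2
  co <- olsLine(f, norm@values)
  list(ss = unname(co["slope"]), si = unname(co["intercept"]),
       mbf = unname(co["intercept"] + co["slope"] * fMid))
}

#' Backscatter coefficient from a normalized spectrum
#'
#' Transfers the known reference-phantom backscatter coefficient through
#' the normalized dB ratio: bsc(f) = bsc_ref(f) * 10^(values(f)/10).
#'
#' @param norm a [NormalizedSpectrumDB-class]
#' @param bscRef a [BscEstimate-class] on the same frequency grid
#' @return a [BscEstimate-class]
#' @export
estimateBsc <- function(norm, bscRef) {
  if (length(norm@freqs) != length(bscRef@freqs) ||
      any(abs(norm@freqs - bscRef@freqs) > 1e-9))
    stop("bscRef must be on the normalized spectrum's frequency grid")
  BscEstimate(norm@freqs, bscRef@bsc * 10^(norm@values / 10))
}

# dB-domain model curves for all grid diameters: G[i, ] = 10 log10 of the
# form-factor model with unit concentration for esdGrid[i]
formFactorGridDb <- function(freqs, esdGrid, soundSpeed) {
  a <- esdGrid / 2 * 1e-6
  k <- 2 * pi * freqs * 1e6 / soundSpeed
  # rows: grid, cols: freq
  outer(60 * log10(a), rep(1, length(k))) +
    outer(rep(1, length(a)), 40 * log10(k)) -
    (10 / log(10)) * 0.827 * outer(a^2, k^2)
}

#' Gaussian form-factor inversion for ESD and EAC
#'
#' Grid search over candidate diameters: for each grid value the dB-domain
#' least-squares intercept (the EAC in dB) is closed-form, and the grid
#' point minimizing the residual sum of squares is returned.
#'
#' @param bsc a [BscEstimate-class] (positive on the band)
#' @param soundSpeed m/s
#' @param esdGrid candidate diameters (um)
#' @return list(esd, eac, rss) -- diameter (um), concentration (dB) and the
#'   residual at the optimum.
#' @export
fitGaussianFormFactor <- function(bsc, soundSpeed = 1540,
                                  esdGrid = seq(1, 300, by = 1)) {
  if (length(esdGrid) < 1L) stop("esdGrid must be non-empty")
  y <- 10 * log10(bsc@bsc)
  G <- formFactorGridDb(bsc@freqs, esdGrid, soundSpeed)
  R <- sweep(-G, 2, y, "+")          # y - g_a per grid row
  b <- rowMeans(R)
  rss <- rowSums((R - b)^2)
  if (!any(is.finite(rss))) stop("degenerate form-factor fit")
  i <- which.min(rss)
  list(esd = esdGrid[i], eac = b[i], rss = rss[i])
}

#' Full spectral-parameter chain for one window
#'
#' Convenience wrapper running [normalizeSpectrum()], [fitLinearBand()],
#' [estimateBsc()] and [fitGaussianFormFactor()] for one gated window
#' against a reference spectrum with a flat backscatter level.
#'
#' @param sample,reference [MeanPowerSpectrum-class] on identical grids
#' @param depthCm window-center depth (cm)
#' @param bscRefLevel flat reference backscatter level
#' @param config a [qusConfig()]
#' @return a [QusEstimate-class]
#' @export
estimateQus <- function(sample, reference, depthCm, bscRefLevel = 1,
                        config = qusConfig()) {
  norm <- normalizeSpectrum(sample, reference, config$alphaSample,
                            config$alphaRef, depthCm, config$band)
  lin <- fitLinearBand(norm, fMid = mean(config$band))
  bsc <- estimateBsc(norm, BscEstimate(norm@freqs,
                                       rep(bscRefLevel, length(norm@freqs))))
  ff <- fitGaussianFormFactor(bsc, config$soundSpeed, config$esdGrid)
  new("QusEstimate", mbf = lin$mbf, ss = lin$ss, si = lin$si,
      esd = ff$esd, eac = ff$eac)
}

#' Export a spectrum as two-column text
#'
#' @param x a [MeanPowerSpectrum-class] or [NormalizedSpectrumDB-class]
#' @param file path
#' @export
writeSpectrum <- function(x, file) {
  if (is(x, "MeanPowerSpectrum"))
    utils::write.table(data.frame(MHz = x@freqs, power = x@power), file,
                       row.names = FALSE, quote = FALSE, sep = "\t")
  else
    utils::write.table(data.frame(MHz = x@freqs, dB = x@values), file,
                       row.names = FALSE, quote = FALSE, sep = "\t")
}
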
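test_that("mean power spectrum obeys basic DFT identities", {
  expect_true(all(meanPowerSpectrum(matrix(0, 64, 3))@power == 0))
  # pure 5 MHz sinusoid at fs = 40 MHz: peak bin at 5 MHz
  t <- (0:255) / 40
  sp <- meanPowerSpectrum(matrix(sin(2 * pi * 5 * t), ncol = 1), 40,
                          nfft = 1024)
  expect_equal(sp@freqs[which.max(sp@power)], 5, tolerance = 0.05)
  expect_error(meanPowerSpectrum(matrix(numeric(0), 0, 0)), "empty")
})

test_that("white-noise mean spectrum is flat across the band", {
  seg <- withr::with_seed(4, matrix(stats::rnorm(128 * 5000), 128, 5000))
  sp <- meanPowerSpectrum(seg, 40)
  band <- sp@power[sp@freqs >= 3 & sp@freqs <= 8]
  expect_lt(max(abs(band / mean(band) - 1)), 0.05)
})

test_that("normalization identities and attenuation compensation hold", {
  f <- seq(0, 20, by = 0.25)
  mk <- function(p) new("MeanPowerSpectrum", freqs = f, power = p,
                        nLines = 10L)
  x <- mk(exp(-f / 4) + 0.5)
  self <- normalizeSpectrum(x, x, 1, 1, 2)
  expect_equal(self@values, rep(0, length(self@values)))
  tenfold <- normalizeSpectrum(mk(10 * x@power), x, 0.7, 0.7, 3)
  expect_equal(tenfold@values, rep(10, length(tenfold@values)))
  comp <- normalizeSpectrum(x, x, 1.076, 0.576, 2)
  expect_equal(comp@values, 4 * comp@freqs, tolerance = 1e-10)
  y <- new("MeanPowerSpectrum", freqs = f + 0.01, power = x@power,
           nLines = 10L)
  expect_error(normalizeSpectrum(x, y, 1, 1, 2), "grid")
  bad <- mk(c(rep(0, 20), x@power[-(1:20)]))
  expect_error(normalizeSpectrum(x, bad, 1, 1, 2), "positive")
})

test_that("linear band regression is exact on affine spectra", {
  f <- seq(3, 8, by = 0.05)
  mkNorm <- function(v) new("NormalizedSpectrumDB", freqs = f, values = v,
                            sampleAttenuation = 1, refAttenuation = 0.576,
                            depth = 2)
  fit <- fitLinearBand(mkNorm(-2 * f + 10))
  expect_equal(fit$ss, -2)
  expect_equal(fit$si, 10)
  expect_equal(fit$mbf, -1)  # evaluated at the 5.5 MHz band midpoint
  flat <- fitLinearBand(mkNorm(rep(3.5, length(f))))
  expect_equal(c(flat$ss, flat$si, flat$mbf), c(0, 3.5, 3.5))
  one <- new("NormalizedSpectrumDB", freqs = 5, values = 1,
             sampleAttenuation = 1, refAttenuation = 1, depth = 1)
  expect_error(fitLinearBand(one), "distinct")
})

test_that("slope recovery under noise matches OLS sampling error", {
  f <- seq(3, 8, length.out = 101)
  slopes <- withr::with_seed(21, vapply(1:100, function(i) {
    v <- -1.7 * f + 6 + stats::rnorm(101, sd = 0.1)
    nd <- new("NormalizedSpectrumDB", freqs = f, values = v,
              sampleAttenuation = 1, refAttenuation = 1, depth = 1)
    fitLinearBand(nd)$ss
  }, numeric(1)))
  expect_true(all(abs(slopes + 1.7) < 0.05))
})

test_that("closed-form OLS agrees with stats::lm", {
  withr::with_seed(8, {
    x <- stats::runif(40, 3, 8)
    y <- 2.3 - 0.8 * x + stats::rnorm(40)
  })
  co <- qusdl:::olsLine(x, y)
  ref <- stats::coef(stats::lm(y ~ x))
  expect_equal(unname(co), unname(ref), tolerance = 1e-10)
})

test_that("backscatter transfer obeys the reference-phantom identity", {
  f <- seq(3, 8, by = 0.1)
  bref <- BscEstimate(f, 0.5 * exp(f / 10))
  mkNorm <- function(v) new("NormalizedSpectrumDB", freqs = f, values = v,
                            sampleAttenuation = 1, refAttenuation = 1,
                            depth = 1)
  expect_equal(estimateBsc(mkNorm(rep(0, length(f))), bref)@bsc, bref@bsc)
  expect_equal(estimateBsc(mkNorm(rep(10, length(f))), bref)@bsc,
               10 * bref@bsc)
  expect_error(estimateBsc(mkNorm(rep(0, length(f))),
                           BscEstimate(f + 0.05, bref@bsc)), "grid")
})

test_that("simulated spectra round-trip to the backscatter model", {
  g <- FrameGeometry(nLines = 3000, nSamples = 256, lateralPitch = 0.05,
                     depthOffset = 10)
  p <- tinyPulse()
  spec <- ScatteringSpec(esd = 80, eacDb = 30, attenuation = 1,
                         soundSpeed = 1540)
  fr <- simulateRFFrame(spec, g, p, seed = 31)
  # reference simulated with the sample's attenuation and sound speed so
  # the compensation term vanishes exactly
  ref <- simulateReferenceFrame(g, p, seed = 32, attenuation = 1,
                                soundSpeed = 1540)
  rows <- 65:168
  sW <- frameSpectrum(fr, rows)
  rW <- frameSpectrum(ref, rows)
  norm <- normalizeSpectrum(sW, rW, 1, 1, sampleDepthMm(g, 116.5) / 10)
  est <- estimateBsc(norm, BscEstimate(norm@freqs,
                                       rep(1, length(norm@freqs))))
  truthBsc <- bscModel(norm@freqs, 80, 30, 1540)
  # compare band-average level and shape within Monte-Carlo error
  expect_equal(mean(est@bsc / truthBsc), 1, tolerance = 0.05)
})

test_that("Gaussian form factor reduces to Rayleigh at zero frequency", {
  expect_equal(gaussianFormFactor(0, 120), 1)
  expect_true(all(diff(gaussianFormFactor(seq(0, 10, 0.5), 80)) < 0))
})

test_that("form-factor inversion recovers noiseless model curves exactly", {
  f <- seq(3, 8, length.out = 64)
  for (truth in list(c(80, 30), c(40, 12), c(150, -5), c(246, 22))) {
    bsc <- BscEstimate(f, bscModel(f, truth[1], truth[2]))
    fit <- fitGaussianFormFactor(bsc)
    expect_equal(fit$esd, truth[1])
    expect_equal(fit$eac, truth[2], tolerance = 0.01)
  }
})

test_that("recovered ESD ordering is preserved across true diameters", {
  f <- seq(3, 8, length.out = 64)
  fits <- vapply(c(20, 60, 120), function(a)
    fitGaussianFormFactor(BscEstimate(f, bscModel(f, a, 20)))$esd,
    numeric(1))
  expect_true(all(diff(fits) > 0))
  expect_equal(fits, c(20, 60, 120))
})

test_that("degenerate form-factor fits are rejected", {
  f <- seq(3, 8, length.out = 16)
  bsc <- BscEstimate(f, bscModel(f, 60, 10))
  expect_error(fitGaussianFormFactor(bsc, esdGrid = numeric(0)),
               "non-empty")
})
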
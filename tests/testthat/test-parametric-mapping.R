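test_that("window positions follow the overlap geometry", {
  expect_equal(windowPositions(20, SlidingGrid(2, 0.95))$count, 181L)
  expect_equal(SlidingGrid(2, 0.95)@step, 0.1)
  expect_equal(windowPositions(2, SlidingGrid(2, 0.95))$count, 1L)
  expect_equal(windowPositions(20, SlidingGrid(2, 0))$count, 10L)
  expect_equal(windowPositions(1.5, SlidingGrid(2, 0.95))$count, 0L)
  centers <- windowPositions(4, SlidingGrid(2, 0.5))$centers
  expect_equal(centers, c(1, 2, 3))
})

test_that("margin dilation produces the expected annulus", {
  grid <- seq(0.05, 40, by = 0.1)
  roi <- RoiContour(ellipsePolygon(20, 20, 10, 10, n = 256))
  m <- dilateMargin(roi, grid, grid, thickness = 5)
  ratio <- sum(m$margin) / sum(m$core)
  expect_equal(ratio, (15^2 - 10^2) / 10^2, tolerance = 0.03)
  expect_true(all(m$core * m$margin == 0))
  m0 <- dilateMargin(roi, grid, grid, thickness = 0)
  expect_equal(sum(m0$margin), 0)
})

test_that("margin band stays within the dilation distance of the core", {
  grid <- seq(0.25, 30, by = 0.5)
  roi <- RoiContour(ellipsePolygon(15, 14, 6, 4, n = 96))
  m <- dilateMargin(roi, grid, grid, thickness = 5)
  d <- EBImage::distmap(1 - m$core) * 0.5
  expect_true(all(d[m$margin > 0] <= 5 + 1e-6))
  expect_true(all(d[m$margin == 0 & m$core == 0] > 5 - 0.5))
})

test_that("margin is clipped at the frame edge without error", {
  grid <- seq(0.25, 20, by = 0.5)
  roi <- RoiContour(ellipsePolygon(4.5, 10, 4, 4, n = 96))  # touches edge
  m <- dilateMargin(roi, grid, grid, thickness = 5,
                    bounds = list(lat = c(0, 20), ax = c(0, 20)))
  expect_identical(dim(m$margin), c(length(grid), length(grid)))
  out <- RoiContour(ellipsePolygon(-3, 10, 2, 2))
  expect_error(dilateMargin(out, grid, grid,
                            bounds = list(lat = c(0, 20), ax = c(0, 20))),
               "outside")
})

test_that("maps recover a homogeneous tumor and stay background elsewhere", {
  g <- mapGeometry()
  spec <- ScatteringSpec(esd = 60, eacDb = 25, attenuation = 1)
  fr <- simulateRFFrame(spec, g, seed = 51)
  ref <- simulateReferenceFrame(g, seed = 52)
  roi <- RoiContour(ellipsePolygon(12, 15, 5, 4))
  img <- generateMaps(fr, ref, roi, SlidingGrid(2, 0.5),
                      marginThickness = 3)
  esd <- channels(img)[, , 3]
  inCore <- coreMask(img) > 0
  expect_lt(abs(stats::median(esd[inCore]) - 60) / 60, 0.10)
  # few-line map windows carry a larger smoothing bias than the deep
  # spectral-averaging case, so the EAC band here is looser
  eac <- channels(img)[, , 4]
  expect_lt(abs(stats::median(eac[inCore]) - 25), 2.5)
  outside <- coreMask(img) + marginMask(img) == 0
  expect_true(all(channels(img)[, , 1][outside] == 0))
  # map pixel grid matches the sliding-window position counts
  lat <- windowPositions(g@nLines * g@lateralPitch, SlidingGrid(2, 0.5))
  expect_equal(dim(channels(img))[2], lat$count)
})

test_that("a contour enclosing no window centers yields all background", {
  g <- mapGeometry()
  fr <- simulateRFFrame(ScatteringSpec(60, 25, 1), g, seed = 3)
  ref <- simulateReferenceFrame(g, seed = 4)
  tiny <- RoiContour(ellipsePolygon(12.53, 15.53, 0.02, 0.02))
  img <- generateMaps(fr, ref, tiny, SlidingGrid(2, 0.5))
  expect_true(all(channels(img) == 0))
})

test_that("core/margin contrast is ordered as the underlying truth", {
  g <- mapGeometry()
  cp <- cohortClassParams()
  cp$responder$core$esd <- 30; cp$responder$margin$esd <- 90
  fld <- ellipseField(12, 14, 4.5, 4, cp, "responder", marginMm = 4)
  fr <- simulateRFFrame(ScatteringSpec(30, 25, 1), g, seed = 61, field = fld)
  ref <- simulateReferenceFrame(g, seed = 62)
  roi <- RoiContour(ellipsePolygon(12, 14, 4.5, 4))
  img <- generateMaps(fr, ref, roi, SlidingGrid(2, 0.5),
                      marginThickness = 4)
  esd <- channels(img)[, , 3]
  expect_lt(stats::median(esd[coreMask(img) > 0]),
            stats::median(esd[marginMask(img) > 0]))
})

test_that("fast in-map estimator equals the exported spectral chain", {
  cfg <- qusConfig()
  f <- seq(3, 8, length.out = 48)
  withr::with_seed(71, {
    sBand <- exp(stats::rnorm(48, sd = 0.3)) * 1e-6
    rBand <- exp(stats::rnorm(48, sd = 0.1)) * 1e-5
  })
  full <- nextPow2(4 * 104)
  # embed the band values into full spectra to run the exported chain
  freqs <- (0:(full / 2)) * 40 / full
  sel <- freqs >= 3 & freqs <= 8
  fBand <- freqs[sel]
  sB <- stats::approx(f, sBand, fBand, rule = 2)$y
  rB <- stats::approx(f, rBand, fBand, rule = 2)$y
  sp <- rp <- rep(1, length(freqs))
  sp[sel] <- sB; rp[sel] <- rB
  sampleSp <- new("MeanPowerSpectrum", freqs = freqs, power = sp,
                  nLines = 10L)
  refSp <- new("MeanPowerSpectrum", freqs = freqs, power = rp, nLines = 10L)
  slow <- estimateQus(sampleSp, refSp, depthCm = 2, bscRefLevel = 1,
                      config = cfg)
  G <- qusdl:::formFactorGridDb(fBand, cfg$esdGrid, cfg$soundSpeed)
  # one call covering several windows at once, first row = the window above
  fast <- qusdl:::estimateQusFast(rbind(sB, 2 * sB, sB / 3), rB, fBand, 2,
                                  cfg, G, 1)
  expect_equal(unname(fast[1, "mbf"]), slow@mbf)
  expect_equal(unname(fast[1, "si"]), slow@si)
  expect_equal(unname(fast[1, "esd"]), slow@esd)
  expect_equal(unname(fast[1, "eac"]), slow@eac)
  # scaling a window by a constant shifts MBF/SI/EAC, leaves SS/ESD
  expect_equal(unname(fast[2, "esd"]), slow@esd)
  expect_equal(unname(fast[2, "si"]), slow@si + 10 * log10(2))
})

test_that("preprocessing normalizes, clips, masks and resizes", {
  ch <- array(0, c(40, 40, 4))
  core <- matrix(0, 40, 40); core[15:26, 15:26] <- 1
  marg <- matrix(0, 40, 40); marg[10:31, 10:31] <- 1; marg <- marg * (1 - core)
  withr::with_seed(5, for (k in 1:4)
    ch[, , k] <- matrix(stats::runif(1600, -10, 10), 40, 40) *
      ((core + marg) > 0))
  img <- ParametricImage(ch, core, marg, pixelPitch = 1)
  np <- computeNormParams(list(img), mode = "core+margin")
  out <- preprocessForNetwork(img, "core+margin", np, size = 64)
  expect_identical(dim(inputTensor(out)), c(64L, 64L, 4L))
  expect_gte(min(inputTensor(out)), 0)
  expect_lte(max(inputTensor(out)), 1)
  # training extremes map exactly to 0 and 1 (output size = mask bounding
  # box, so resampling is the identity and the min-max identity is exact)
  outId <- preprocessForNetwork(img, "core+margin", np, size = 22)
  expect_equal(max(inputTensor(outId)), 1)
  expect_equal(min(inputTensor(outId)), 0)
  # values above the training max are clipped to 1
  npLow <- np; npLow$max <- np$max / 2
  outLow <- preprocessForNetwork(img, "core+margin", npLow, size = 64)
  expect_equal(max(inputTensor(outLow)), 1)
  # provenance guard: parameters not from a training set are refused
  npTest <- computeNormParams(list(img), role = "test")
  expect_error(preprocessForNetwork(img, "core+margin", npTest), "training")
  npBad <- np; npBad$max <- npBad$min
  expect_error(preprocessForNetwork(img, "core+margin", npBad), "degenerate")
  empty <- ParametricImage(ch, core * 0, marg * 0, pixelPitch = 1)
  expect_error(preprocessForNetwork(empty, "core", np), "empty mask")
})

test_that("core values agree between input modes up to resampling", {
  ch <- array(0, c(40, 40, 4))
  core <- matrix(0, 40, 40); core[12:29, 12:29] <- 1
  marg <- matrix(0, 40, 40); marg[6:35, 6:35] <- 1; marg <- marg * (1 - core)
  for (k in 1:4) ch[, , k] <- (core * 5 + marg * 2) * k
  img <- ParametricImage(ch, core, marg, pixelPitch = 1)
  np <- computeNormParams(list(img), mode = "core+margin")
  a <- inputTensor(preprocessForNetwork(img, "core", np, size = 64))
  b <- inputTensor(preprocessForNetwork(img, "core+margin", np, size = 64))
  for (k in 1:4)
    expect_equal(stats::median(a[, , k][a[, , k] > 0]),
                 stats::median(b[, , k][b[, , k] > (2 * k - 2) / 20]),
                 tolerance = 0.05)
})
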
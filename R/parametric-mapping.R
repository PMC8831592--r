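## Sliding-window parametric maps over a tumor core plus margin band, and
## fixed-size normalized network inputs.

#' Sliding-window positions along one axis
#'
#' Window centers are placed at windowSize/2 + i*step while the full window
#' fits inside the extent; with 2 mm windows and 95% overlap the step is
#' 0.1 mm and a 20 mm extent holds 181 positions.
#'
#' @param roiExtent axis extent (mm)
#' @param grid a [SlidingGrid-class]
#' @return list(count, centers) -- centers relative to the extent start (mm).
#' @export
windowPositions <- function(roiExtent, grid) {
  w <- grid@windowSize; s <- grid@step
  if (roiExtent < w - 1e-9) return(list(count = 0L, centers = numeric(0)))
  count <- as.integer(floor((roiExtent - w) / s + 1e-9) + 1)
  list(count = count, centers = w / 2 + (seq_len(count) - 1) * s)
}

#' Core and margin masks on a pixel-center grid
#'
#' Rasterizes the core contour on the supplied pixel centers and derives the
#' margin band: all pixels outside the core whose Euclidean distance to the
#' core is at most `thickness` mm, clipped to the grid. Pixels are rows =
#' axial centers, cols = lateral centers.
#'
#' @param roi a [RoiContour-class]
#' @param latCenters,axCenters pixel-center coordinates (mm)
#' @param thickness margin thickness (mm), default 5
#' @param bounds optional frame bounds list(lat = c(lo, hi), ax = c(lo, hi));
#'   a contour vertex outside the bounds is an error
#' @return list(core, margin): binary matrices, disjoint.
#' @export
dilateMargin <- function(roi, latCenters, axCenters, thickness = 5,
                         bounds = NULL) {
  if (!is.null(bounds)) {
    v <- roi@polygon
    if (any(v[, 1] < bounds$lat[1] - 1e-9 | v[, 1] > bounds$lat[2] + 1e-9 |
            v[, 2] < bounds$ax[1] - 1e-9 | v[, 2] > bounds$ax[2] + 1e-9))
      stop("contour lies outside the frame bounds")
  }
  nAx <- length(axCenters); nLat <- length(latCenters)
  pts <- cbind(rep(latCenters, each = nAx), rep(axCenters, times = nLat))
  inside <- mgcv::in.out(rbind(roi@polygon, roi@polygon[1, ]), pts)
  core <- matrix(as.numeric(inside), nAx, nLat)
  if (thickness <= 0 || sum(core) == 0)
    return(list(core = core, margin = matrix(0, nAx, nLat)))
  pitchLat <- if (nLat > 1) diff(latCenters[1:2]) else 1
  pitchAx <- if (nAx > 1) diff(axCenters[1:2]) else 1
  pitch <- (pitchLat + pitchAx) / 2
  d <- EBImage::distmap(1 - core) * pitch
  margin <- (core == 0) & (d <= thickness + 1e-9)
  list(core = core, margin = matrix(as.numeric(margin), nAx, nLat))
}

# fast spectral chain for a whole row of windows at one depth, vectorized
# over windows; numerically identical to estimateQus() per window (asserted
# in the tests). `S` is windows x band-frequencies (a vector is one window).
# The grid fit uses the centered decomposition
#   rss(win, a) = sum(yc^2) + sum(gc^2) - 2 yc . gc
# so the whole row needs a single matrix product against the grid curves.
estimateQusFast <- function(S, rBand, fBand, depthCm, cfg, G, bscRefLevel) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  comp <- 4 * (cfg$alphaSample - cfg$alphaRef) * fBand * depthCm
  V <- sweep(10 * log10(sweep(S, 2, rBand, "/")), 2, comp, "+")
  fc <- fBand - mean(fBand)
  slope <- drop(V %*% fc) / sum(fc^2)
  rowBar <- rowMeans(V)
  intercept <- rowBar - slope * mean(fBand)
  Vb <- rowBar + 10 * log10(bscRefLevel)
  Yc <- V - rowBar
  Gbar <- rowMeans(G)
  Gc <- G - Gbar
  rss <- rowSums(Yc^2) + rep(1, nrow(V)) %o% rowSums(Gc^2) -
    2 * Yc %*% t(Gc)
  i <- max.col(-rss, ties.method = "first")
  cbind(mbf = intercept + slope * mean(cfg$band), si = intercept,
        ss = slope, esd = cfg$esdGrid[i], eac = Vb - Gbar[i])
}

#' Generate a multi-parametric image for one scan plane
#'
#' Runs the full spectral chain for every sliding window whose center falls
#' inside the tumor core or its margin band, assigning the MBF, SI, ESD and
#' EAC estimates to the window-center pixel. The map pixel pitch equals the
#' window step. The reference spectrum for each window is taken from the
#' reference frame at the same depth, averaged over all its scan lines.
#' Pixels with no analyzed window are 0 (background).
#'
#' @param frame sample [RFFrame-class]
#' @param refFrame reference-phantom [RFFrame-class] (same pulse/geometry
#'   convention, depth coverage at least the sample's)
#' @param roi a [RoiContour-class] for the tumor core
#' @param grid a [SlidingGrid-class]
#' @param config a [qusConfig()]
#' @param marginThickness margin band thickness (mm)
#' @param refCache optional environment caching the reference row spectra
#'   keyed by gate start index; pass one environment across the planes of
#'   a cohort sharing a reference frame to avoid recomputation
#' @return a [ParametricImage-class]
#' @export
generateMaps <- function(frame, refFrame, roi, grid, config = qusConfig(),
                         marginThickness = 5, refCache = NULL) {
  g <- frame@geometry
  gr <- refFrame@geometry
  if (abs(g@axialPitch - gr@axialPitch) > 1e-9 ||
      gr@nSamples < g@nSamples)
    stop("reference frame incompatible with the sample frame")
  fs <- frame@pulse@samplingFrequency
  w <- grid@windowSize
  latExtent <- g@nLines * g@lateralPitch
  axExtent <- g@nSamples * g@axialPitch
  latPos <- windowPositions(latExtent, grid)
  axPos <- windowPositions(axExtent, grid)
  if (latPos$count == 0L || axPos$count == 0L)
    stop("frame smaller than one analysis window")
  latC <- latPos$centers
  axC <- g@depthOffset + axPos$centers
  masks <- dilateMargin(roi, latC, axC, thickness = marginThickness,
                        bounds = list(lat = c(0, latExtent),
                                      ax = c(g@depthOffset,
                                             g@depthOffset + axExtent)))
  sel <- masks$core + masks$margin > 0
  chans <- array(0, c(length(axC), length(latC), 4))
  if (any(sel)) {
    nGate <- max(2L, round(w / g@axialPitch))
    nfft <- nextPow2(config$nfftFactor * nGate)
    half <- seq_len(nfft %/% 2 + 1)
    freqs <- (half - 1) * fs / nfft
    bandSel <- freqs >= config$band[1] - 1e-9 & freqs <= config$band[2] + 1e-9
    fBand <- freqs[bandSel]
    G <- formFactorGridDb(fBand, config$esdGrid, config$soundSpeed)
    bscRefLevel <- if (!is.null(refFrame@truth$bscRef))
      refFrame@truth$bscRef else 1
    h <- hannWindow(nGate)
    nLinesWin <- max(1L, round(w / g@lateralPitch))
    halfLines <- (nLinesWin - 1) / 2
    for (ia in seq_len(length(axC))) {
      cols <- which(sel[ia, ])
      if (length(cols) == 0L) next
      i0 <- round((axC[ia] - w / 2 - g@depthOffset) / g@axialPitch) + 1
      i0 <- min(max(i0, 1L), g@nSamples - nGate + 1L)
      idx <- i0:(i0 + nGate - 1L)
      pad <- matrix(0, nfft, g@nLines)
      pad[seq_len(nGate), ] <- frame@samples[idx, ] * h
      P <- Mod(stats::mvfft(pad)[half, , drop = FALSE])^2
      key <- as.character(i0)
      rBand <- if (!is.null(refCache)) refCache[[key]] else NULL
      if (is.null(rBand)) {
        padR <- matrix(0, nfft, gr@nLines)
        padR[seq_len(nGate), ] <- refFrame@samples[idx, ] * h
        rBand <- rowMeans(Mod(stats::mvfft(padR)[half,
                                                 , drop = FALSE])^2)[bandSel]
        if (!is.null(refCache)) refCache[[key]] <- rBand
      }
      Pc <- cbind(0, t(apply(P[bandSel, , drop = FALSE], 1, cumsum)))
      jc <- latC[cols] / g@lateralPitch + 1
      j0 <- pmax(1L, as.integer(round(jc - halfLines)))
      j1 <- pmin(g@nLines, j0 + nLinesWin - 1L)
      S <- (t(Pc[, j1 + 1, drop = FALSE]) - t(Pc[, j0, drop = FALSE])) /
        (j1 - j0 + 1)
      est <- estimateQusFast(S, rBand, fBand, axC[ia] / 10, config, G,
                             bscRefLevel)
      chans[ia, cols, ] <- est[, c("mbf", "si", "esd", "eac")]
    }
  }
  ParametricImage(chans, masks$core, masks$margin, pixelPitch = grid@step)
}

#' Per-channel normalization parameters from a training set
#'
#' Global per-channel (min, max) over the in-ROI pixels of the supplied
#' parametric images. The returned object carries a provenance role;
#' [preprocessForNetwork()] refuses parameters not derived from a training
#' set, so test-set leakage is structurally prevented.
#'
#' @param images list of [ParametricImage-class]
#' @param mode "core" or "core+margin" (which mask defines in-ROI)
#' @param role provenance tag; must be "training" for downstream use
#' @export
computeNormParams <- function(images, mode = "core+margin",
                              role = "training") {
  lo <- rep(Inf, 4); hi <- rep(-Inf, 4)
  for (img in images) {
    m <- img@coreMask
    if (mode == "core+margin") m <- m + img@marginMask
    keep <- m > 0
    for (ch in 1:4) {
      v <- img@channels[, , ch][keep]
      if (length(v)) {
        lo[ch] <- min(lo[ch], min(v))
        hi[ch] <- max(hi[ch], max(v))
      }
    }
  }
  structure(list(min = lo, max = hi, mode = mode, role = role),
            class = "qusNormParams")
}

#' Prepare a fixed-size normalized network input
#'
#' Zeroes pixels outside the selected mask, crops to the mask bounding box,
#' resamples bilinearly to `size` x `size`, min-max normalizes each channel
#' with training-set parameters and clips to [0, 1]. Pixels outside the
#' (resampled) mask are held at 0, the background convention occlusion
#' analysis relies on.
#'
#' @param img a [ParametricImage-class]
#' @param mode "core" or "core+margin"
#' @param normParams a [computeNormParams()] result with role "training"
#' @param size output side (pixels)
#' @return a [NetworkInput-class]
#' @export
preprocessForNetwork <- function(img, mode = c("core+margin", "core"),
                                 normParams, size = 512) {
  mode <- match.arg(mode)
  if (!inherits(normParams, "qusNormParams") ||
      !identical(normParams$role, "training"))
    stop("normParams must be derived from the training set")
  if (any(normParams$max <= normParams$min))
    stop("degenerate normalization range (max <= min)")
  m <- img@coreMask
  if (mode == "core+margin") m <- m + img@marginMask
  if (sum(m) == 0) stop("degenerate bounding box: empty mask")
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  if (diff(rows) < 1 || diff(cols) < 1)
    stop("degenerate bounding box")
  crop <- img@channels[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  mCrop <- m[rows[1]:rows[2], cols[1]:cols[2]]
  big <- EBImage::resize(crop, w = size, h = size)
  mBig <- EBImage::resize(mCrop, w = size, h = size) > 0.5
  out <- array(0, c(size, size, 4))
  for (ch in 1:4) {
    v <- (big[, , ch] - normParams$min[ch]) /
      (normParams$max[ch] - normParams$min[ch])
    v <- pmin(pmax(v, 0), 1)
    v[!mBig] <- 0
    out[, , ch] <- v
  }
  NetworkInput(out, mode = mode)
}

#' Write / read contours as CSV vertex lists (mm coordinates)
#'
#' @param roi a [RoiContour-class]
#' @param file path
#' @export
writeContour <- function(roi, file) {
  utils::write.csv(data.frame(lateral_mm = roi@polygon[, 1],
                              axial_mm = roi@polygon[, 2],
                              plane = roi@planeId),
                   file, row.names = FALSE)
}

#' @rdname writeContour
#' @export
readContour <- function(file) {
  df <- utils::read.csv(file)
  RoiContour(cbind(df$lateral_mm, df$axial_mm),
             planeId = as.character(df$plane[1]))
}
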
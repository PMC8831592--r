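## Internal helpers shared across modules.

# axial sample spacing in mm: round-trip distance per RF sample
axialPitchMm <- function(soundSpeed, samplingFrequency) {
  soundSpeed / (2000 * samplingFrequency)
}

# signed polygon area (shoelace), mm^2
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

nextPow2 <- function(n) 2^ceiling(log2(n))

hannWindow <- function(n) {
  if (n == 1) return(1)
  signal::hanning(n)
}

# largest-remainder allocation of `total` items proportional to `weights`
largestRemainder <- function(weights, total) {
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# depth (mm) of sample index i (1-based) in a frame geometry
sampleDepthMm <- function(geometry, i) {
  geometry@depthOffset + (i - 1) * geometry@axialPitch
}

# lateral position (mm) of line j (1-based)
lineLateralMm <- function(geometry, j) (j - 1) * geometry@lateralPitch

responseLevels <- c("responder", "non-responder")

assertLabels <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% responseLevels))
    stop("labels must be 'responder' or 'non-responder'")
  labels
}

#' Channel order of parametric images
#'
#' @return character vector of the fixed channel order.
#' @export
qusChannels <- function() c("MBF", "SI", "ESD", "EAC")
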
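# Shared desk-scale fixtures. Everything is generated in code; frames are
# deliberately small so the whole suite stays fast.

tinyPulse <- function() AcousticPulse()

# ~16 x 18 mm frame, coarse lateral pitch (deep enough for a small tumor
# plus its 5 mm margin)
tinyGeometry <- function(nLines = 16, nSamples = 920, lateralPitch = 1,
                         depthOffset = 5)
  FrameGeometry(nLines = nLines, nSamples = nSamples,
                lateralPitch = lateralPitch, depthOffset = depthOffset)

# desk-scale plane used for map tests: 24 x ~23 mm
mapGeometry <- function()
  FrameGeometry(nLines = 120, nSamples = 1200, lateralPitch = 0.2,
                depthOffset = 6)

tinyCohort <- function(n = 6, frac = 0.5, seed = 42) {
  simulateCohort(n, frac, geometry = tinyGeometry(),
                 tumorDiameterRange = c(4, 6), seed = seed)
}

# uniform random 4-channel input of side `size` in [0,1]
randomInput <- function(size = 32, seed = 1) {
  withr::with_seed(seed,
    NetworkInput(array(stats::runif(size * size * 4), c(size, size, 4))))
}

# mean power spectrum of an axial sample range of a frame
frameSpectrum <- function(frame, rows, nfft = NULL) {
  meanPowerSpectrum(rfSamples(frame)[rows, , drop = FALSE],
                    framePulse(frame)@samplingFrequency, nfft = nfft)
}
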
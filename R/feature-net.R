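## Convolutional feature network: residual (ResNet-style) or
## residual-attention (RAN-style) backbone over 4-channel parametric
## images, trained on single planes with the patient response as the
## plane label, exposing a 256-d feature vector.

#' Backbone configuration
#'
#' @param architecture "ran" (residual attention) or "resnet" (residual)
#' @param depthPreset "small" (one residual/attention stage per resolution,
#'   the desk-scale variant) or "full" (deep variant: 3-4-23-3 residual
#'   stages, or three attention stages of 1/2/3 modules plus a residual
#'   tail; reduced width relative to the GPU-scale originals)
#' @param inputSize side of the square network input (pixels); the stem
#'   average-pools inputs larger than 32 px to a 32 px working resolution
#' @param inChannels number of input channels, fixed at 4 (MBF,SI,ESD,EAC)
#' @param featureDim feature vector length, fixed at 256
#' @param nClasses number of output classes, fixed at 2
#' @param baseWidth channels after the stem convolution
#' @export
backboneConfig <- function(architecture = c("ran", "resnet"),
                           depthPreset = c("small", "full"),
                           inputSize = 512, inChannels = 4,
                           featureDim = 256, nClasses = 2, baseWidth = 8) {
  architecture <- match.arg(architecture)
  depthPreset <- match.arg(depthPreset)
  if (featureDim != 256) stop("featureDim is fixed at 256")
  if (inChannels != 4) stop("inChannels is fixed at 4")
  stemPool <- if (inputSize > 32) inputSize %/% 32L else 1L
  if (stemPool * 32L != inputSize && inputSize > 32)
    stop("inputSize must be a multiple of 32 (or <= 32)")
  structure(list(architecture = architecture, depthPreset = depthPreset,
                 inputSize = as.integer(inputSize), inChannels = inChannels,
                 featureDim = featureDim, nClasses = nClasses,
                 baseWidth = as.integer(baseWidth),
                 stemPool = as.integer(stemPool)),
            class = "qusBackboneConfig")
}

#' Training configuration
#'
#' Defaults are the optimized training hyperparameters: Adam, learning rate
#' 1e-4, batch size 8, dropout 0.5 and a 5:1 cost weight on the
#' non-responder class to counter the class imbalance; augmentation is
#' stochastic horizontal flipping and lateral/axial shifting up to 30% of
#' the image size.
#'
#' @param learningRate Adam learning rate
#' @param batchSize minibatch size
#' @param dropout dropout rate in the fully connected layers
#' @param classWeight cost-weight ratio C (non-responder : responder), >= 1
#' @param maxEpochs training-epoch cap
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement)
#' @param hflip enable horizontal flipping
#' @param shiftMaxFraction maximum shift, fraction of image size, in [0, 1)
#' @param seed governs weight init, batch order and augmentation draws
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 8, dropout = 0.5,
                        classWeight = 5, maxEpochs = 60, patience = 10,
                        hflip = TRUE, shiftMaxFraction = 0.3, seed = 1L) {
  if (classWeight < 1) stop("classWeight must be >= 1")
  if (shiftMaxFraction < 0 || shiftMaxFraction >= 1)
    stop("shiftMaxFraction must be in [0, 1)")
  structure(list(learningRate = learningRate, batchSize = batchSize,
                 dropout = dropout, classWeight = classWeight,
                 maxEpochs = maxEpochs, patience = patience, hflip = hflip,
                 shiftMaxFraction = shiftMaxFraction,
                 seed = as.integer(seed)),
            class = "qusTrainConfig")
}

buildBackboneNode <- function(config) {
  w <- config$baseWidth
  stage1 <- function(width) {
    if (config$architecture == "ran") attentionModule(width)
    else residualBlock(width, width)
  }
  if (config$depthPreset == "small") {
    nnSeq(nnConv(config$inChannels, w), nnRelu(),
          stage1(w), nnRelu(),
          nnPool(2),
          residualBlock(w, 2 * w), nnRelu(),
          nnPool(2),
          nnGap(), nnDense(2 * w, config$featureDim))
  } else if (config$architecture == "resnet") {
    blocks <- c(3, 4, 23, 3)
    layers <- list(nnConv(config$inChannels, w), nnRelu())
    width <- w
    for (s in seq_along(blocks)) {
      outW <- w * 2^(s - 1)
      for (bl in seq_len(blocks[s])) {
        layers <- c(layers, list(residualBlock(width, outW), nnRelu()))
        width <- outW
      }
      if (s < length(blocks)) layers <- c(layers, list(nnPool(2)))
    }
    layers <- c(layers, list(nnGap(), nnDense(width, config$featureDim)))
    do.call(nnSeq, layers)
  } else {
    nAttn <- c(1, 2, 3)
    layers <- list(nnConv(config$inChannels, w), nnRelu())
    width <- w
    for (s in seq_along(nAttn)) {
      outW <- w * 2^(s - 1)
      layers <- c(layers, list(residualBlock(width, outW), nnRelu()))
      width <- outW
      for (m in seq_len(nAttn[s]))
        layers <- c(layers, list(attentionModule(width)))
      if (s < length(nAttn)) layers <- c(layers, list(nnPool(2)))
    }
    for (bl in 1:3)
      layers <- c(layers, list(residualBlock(width, width), nnRelu()))
    layers <- c(layers, list(nnGap(), nnDense(width, config$featureDim)))
    do.call(nnSeq, layers)
  }
}

#' Build an (untrained) feature network
#'
#' Assembles the backbone (stem average-pool to the 32 px working
#' resolution, convolutional stages, global average pooling and a linear
#' projection to 256 features) plus the plane-level training head
#' (256 -> 100 -> 2 with dropout). Weight initialization draws from the
#' current RNG state.
#'
#' @param config a [backboneConfig()]
#' @param dropout dropout rate in the training head
#' @return object of class `qusFeatureNet`.
#' @export
buildFeatureNet <- function(config = backboneConfig(), dropout = 0.5) {
  structure(list(stemPool = config$stemPool,
                 backbone = buildBackboneNode(config),
                 head = nnSeq(nnDense(config$featureDim, 100), nnRelu(),
                              nnDropout(dropout),
                              nnDense(100, config$nClasses)),
                 config = config, history = NULL),
            class = "qusFeatureNet")
}

inputToArray <- function(input) {
  if (is(input, "NetworkInput")) input@tensor
  else if (is.array(input) && length(dim(input)) == 3L) input
  else stop("input must be a NetworkInput or an H x W x 4 array")
}

# pool a plane to the stem working resolution; accepts inputs that are
# already at working resolution (memory-light pipeline path)
toWorkingRes <- function(input, config) {
  x <- inputToArray(input)
  d <- dim(x)
  if (d[1] == config$inputSize) poolArray(x, config$stemPool)
  else if (d[1] * config$stemPool == config$inputSize) x
  else stop("input shape does not match the network configuration")
}

#' Train the feature network on single-plane images
#'
#' Planes are independent samples labelled with their patient's response.
#' Minimizes class-weighted cross-entropy (weight C on non-responders) with
#' Adam, stochastic augmentation per presentation, and early stopping on
#' the validation loss. Deterministic given `cfg$seed`. Augmentation is
#' applied at the stem-pooled working resolution, so shifts are quantized
#' to stem-pool multiples of the input pixel pitch.
#'
#' @param trainInputs list of [NetworkInput-class] (or H x W x 4 arrays)
#' @param trainLabels plane labels ("responder"/"non-responder")
#' @param valInputs,valLabels optional validation planes for early stopping
#' @param backbone a [backboneConfig()]
#' @param cfg a [trainConfig()]
#' @return a trained `qusFeatureNet` with a `history` data.frame
#'   (epoch, trainLoss, valLoss, valAcc).
#' @export
trainFeatureNet <- function(trainInputs, trainLabels, valInputs = NULL,
                            valLabels = NULL, backbone = backboneConfig(),
                            cfg = trainConfig()) {
  withr::with_seed(cfg$seed, {
    net <- buildFeatureNet(backbone, cfg$dropout)
    xs <- lapply(trainInputs, toWorkingRes, config = backbone)
    vxs <- if (is.null(valInputs)) NULL
    else lapply(valInputs, toWorkingRes, config = backbone)
    full <- nnSeq(net$backbone, net$head)
    aug <- function(x) augmentImage(x, cfg$hflip, cfg$shiftMaxFraction)
    fit <- trainNet(full, xs, trainLabels, vxs, valLabels, cfg, augment = aug)
    net$backbone <- fit$node$children[[1]]
    net$head <- fit$node$children[[2]]
    net$history <- fit$history
    net
  })
}

#' Extract the 256-d feature vector of one plane
#'
#' Deterministic inference pass (dropout off) through the backbone.
#'
#' @param net a `qusFeatureNet`
#' @param input a [NetworkInput-class] or H x W x 4 array matching the
#'   configured input size
#' @return numeric vector of length 256.
#' @export
extractFeatures <- function(net, input) {
  x <- inputToArray(input)
  d <- dim(x)
  if (d[1] != net$config$inputSize || d[2] != net$config$inputSize ||
      d[3] != net$config$inChannels)
    stop("input shape does not match the network configuration")
  nnForward(net$backbone, poolArray(x, net$stemPool), train = FALSE)
}

# plane-level class probabilities (used by tests/diagnostics)
planeProbabilities <- function(net, input) {
  feat <- extractFeatures(net, input)
  softmaxVec(nnForward(net$head, feat, train = FALSE))
}

#' Forward pass of a residual block
#'
#' @param block a [residualBlock()]
#' @param x input array
#' @export
residualForward <- function(block, x) nnForward(block, x)

#' Forward pass of an attention module
#'
#' @param module an [attentionModule()]
#' @param x input array
#' @param maskValue if non-NULL, overrides the mask branch output with this
#'   constant (e.g. 0 or 1) to probe the attention-residual limits
#'   y = (1+M)*T
#' @export
attentionForward <- function(module, x, maskValue = NULL) {
  if (is.null(maskValue)) return(nnForward(module, x))
  Tr <- nnForward(module$trunk, x)
  (1 + array(maskValue, dim(Tr))) * Tr
}

#' @export
print.qusFeatureNet <- function(x, ...) {
  np <- sum(vapply(flattenParams(nodeParams(x$backbone)), length, numeric(1)),
            vapply(flattenParams(nodeParams(x$head)), length, numeric(1)))
  cat(sprintf("qusFeatureNet: %s/%s, input %d px (stem pool %d), %d params%s\n",
              x$config$architecture, x$config$depthPreset,
              x$config$inputSize, x$stemPool, np,
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}
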
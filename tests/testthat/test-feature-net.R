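test_that("residual blocks reduce to the identity with zero weights", {
  blk <- qusdl:::zeroNodeParams(residualBlock(3, 3))
  x <- withr::with_seed(1, array(stats::rnorm(6 * 6 * 3), c(6, 6, 3)))
  expect_equal(residualForward(blk, x), x)
  # gradient still flows through the skip connection
  g <- nnGrad(blk, x, array(1, c(6, 6, 3)))
  expect_gt(sum(abs(g$dx)), 0)
  expect_equal(g$dx, array(1, c(6, 6, 3)))  # pure identity path
})

test_that("channel-changing residual blocks use a projection shortcut", {
  blk <- withr::with_seed(2, residualBlock(3, 5))
  x <- withr::with_seed(3, array(stats::rnorm(8 * 8 * 3), c(8, 8, 3)))
  y <- residualForward(blk, x)
  expect_identical(dim(y), c(8L, 8L, 5L))
  bad <- blk; bad$shortcut <- NULL
  expect_error(residualForward(bad, x), "shape mismatch")
})

test_that("attention modules satisfy the attention-residual limits", {
  am <- withr::with_seed(4, attentionModule(3))
  x <- withr::with_seed(5, array(stats::rnorm(8 * 8 * 3), c(8, 8, 3)))
  Tr <- nnForward(am$trunk, x)
  expect_equal(attentionForward(am, x, maskValue = 0), Tr)
  expect_equal(attentionForward(am, x, maskValue = 1), 2 * Tr)
  M <- nnForward(am$mask, x)
  expect_true(all(M > 0 & M < 1))
  expect_equal(nnForward(am, x), (1 + M) * Tr)
})

test_that("analytic gradients match finite differences", {
  node <- withr::with_seed(6, nnSeq(nnConv(2, 3), nnRelu(),
                                    residualBlock(3, 3), nnPool(2),
                                    attentionModule(3), nnGap(),
                                    nnDense(3, 2)))
  x <- withr::with_seed(7, array(stats::rnorm(8 * 8 * 2), c(8, 8, 2)))
  dy <- c(1, -0.5)
  g <- nnGrad(node, x, dy)
  f <- function(xx) sum(nnForward(node, xx) * dy)
  eps <- 1e-6
  for (ii in withr::with_seed(8, sample(length(x), 6))) {
    xp <- x; xp[ii] <- xp[ii] + eps
    xm <- x; xm[ii] <- xm[ii] - eps
    expect_equal(g$dx[ii], (f(xp) - f(xm)) / (2 * eps), tolerance = 1e-5)
  }
  params <- qusdl:::flattenParams(qusdl:::nodeParams(node))
  grads <- qusdl:::flattenParams(g$grads)
  for (pi in c(1, 3, 7)) {
    pp <- params; pp[[pi]][1] <- pp[[pi]][1] + eps
    pm <- params; pm[[pi]][1] <- pm[[pi]][1] - eps
    num <- (f2 <- sum(nnForward(qusdl:::setNodeParams(node, pp), x) * dy) -
              sum(nnForward(qusdl:::setNodeParams(node, pm), x) * dy)) /
      (2 * eps)
    expect_equal(grads[[pi]][1], num, tolerance = 1e-5)
  }
})

test_that("class-weighted loss matches the hand-computed weighted sum", {
  logits <- list(c(1.2, -0.4), c(-0.3, 0.8), c(0.1, 0.1), c(2, -1))
  labels <- c(1L, 2L, 2L, 1L)
  weights <- c(1, 5, 5, 1)
  total <- 0
  for (i in seq_along(logits)) {
    p <- exp(logits[[i]]) / sum(exp(logits[[i]]))
    total <- total + weights[i] * (-log(p[labels[i]]))
    lo <- qusdl:::weightedCELoss(logits[[i]], labels[i], weights[i])
    expect_equal(lo$loss, weights[i] * (-log(p[labels[i]])))
    # C = 1 reduces to the standard cross-entropy
    lo1 <- qusdl:::weightedCELoss(logits[[i]], labels[i], 1)
    expect_equal(lo1$loss, -log(p[labels[i]]))
  }
  expect_equal(total / 4,
               mean(mapply(function(l, y, w)
                 qusdl:::weightedCELoss(l, y, w)$loss,
                 logits, labels, weights)))
})

test_that("feature network configuration enforces the fixed dimensions", {
  expect_error(backboneConfig(featureDim = 128), "256")
  expect_error(backboneConfig(inChannels = 3), "fixed at 4")
  expect_error(backboneConfig(inputSize = 100), "multiple of 32")
  bc <- backboneConfig("resnet", "small", inputSize = 64)
  expect_equal(bc$stemPool, 2L)
})

test_that("both architectures and presets build and run forward", {
  for (arch in c("resnet", "ran")) {
    for (preset in c("small", "full")) {
      bc <- backboneConfig(arch, preset, inputSize = 32)
      net <- withr::with_seed(9, buildFeatureNet(bc))
      x <- withr::with_seed(10, array(stats::runif(32 * 32 * 4),
                                      c(32, 32, 4)))
      f <- extractFeatures(net, x)
      expect_length(f, 256)
      expect_true(all(is.finite(f)))
    }
  }
})

test_that("feature extraction is deterministic and shape-checked", {
  bc <- backboneConfig("ran", "small", inputSize = 32)
  net <- withr::with_seed(11, buildFeatureNet(bc))
  a <- randomInput(32, 1); b <- randomInput(32, 2)
  fa <- extractFeatures(net, a)
  expect_identical(fa, extractFeatures(net, a))
  expect_false(identical(fa, extractFeatures(net, b)))
  expect_error(extractFeatures(net, randomInput(64, 1)), "shape")
})

test_that("the small variant overfits strongly separated planes", {
  mk <- function(level, seed) withr::with_seed(seed,
    array(pmin(pmax(level + stats::rnorm(64 * 64 * 4, sd = 0.05), 0), 1),
          c(64, 64, 4)))
  xs <- c(lapply(1:8, function(i) mk(0.2, i)),
          lapply(9:16, function(i) mk(0.8, i)))
  ys <- rep(c("responder", "non-responder"), each = 8)
  net <- trainFeatureNet(xs, ys, backbone = backboneConfig("ran", "small",
                                                           inputSize = 64),
                         cfg = trainConfig(maxEpochs = 100, seed = 7))
  pred <- vapply(xs, function(x)
    which.max(qusdl:::planeProbabilities(net, x)), integer(1))
  expect_equal(mean(pred == rep(1:2, each = 8)), 1)
  # loss decreases over the first epochs
  expect_lt(mean(net$history$trainLoss[20:25]),
            mean(net$history$trainLoss[1:5]))
})

test_that("training is deterministic given the seed", {
  mk <- function(seed) withr::with_seed(seed,
    array(stats::runif(32 * 32 * 4), c(32, 32, 4)))
  xs <- lapply(1:8, mk)
  ys <- rep(c("responder", "non-responder"), 4)
  bc <- backboneConfig("resnet", "small", inputSize = 32)
  n1 <- trainFeatureNet(xs, ys, xs, ys, bc,
                        trainConfig(maxEpochs = 4, seed = 5))
  n2 <- trainFeatureNet(xs, ys, xs, ys, bc,
                        trainConfig(maxEpochs = 4, seed = 5))
  expect_identical(n1$history, n2$history)
  expect_identical(extractFeatures(n1, xs[[1]]), extractFeatures(n2, xs[[1]]))
  expect_error(trainFeatureNet(xs, rep("responder", 8), backbone = bc,
                               cfg = trainConfig(maxEpochs = 1)),
               "both classes")
})
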
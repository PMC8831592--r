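## Minimal feed-forward network engine.
##
## Networks are trees of typed nodes ("conv", "dense", "relu", "sigmoid",
## "pool", "upsample", "gap", "dropout", "seq", "residual", "attention").
## Spatial activations are numeric arrays [H, W, C]; after global average
## pooling they are plain numeric vectors. Convolutions are evaluated as
## im2col gathers followed by one matrix multiply (BLAS), which keeps the
## desk-scale models fast in pure R. Gradients are hand-derived per node
## and verified against finite differences in the test-suite.

.convIdxCache <- new.env(parent = emptyenv())

# linear gather indices into the zero-padded array for a kxk same-conv
convIndices <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "x")
  hit <- .convIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1) %/% 2
  Hp <- H + 2 * p; Wp <- W + 2 * p
  base <- rep(seq_len(H), times = W) + (rep(seq_len(W), each = H) - 1) * Hp
  offSpatial <- rep(0:(k - 1), times = k) + rep(0:(k - 1), each = k) * Hp
  offAll <- as.vector(outer(offSpatial, (seq_len(C) - 1) * Hp * Wp, "+"))
  idx <- outer(base, offAll, "+")
  .convIdxCache[[key]] <- idx
  idx
}

# stride-1 same-padding correlation via im2col gather + one matmul.
# W is [k, k, inC, outC]; returns the (H*W) x outC response matrix and the
# gathered patch matrix (needed for the weight gradient).
convSame <- function(x, W) {
  d <- dim(x); k <- dim(W)[1]; p <- (k - 1) %/% 2
  if (p > 0) {
    xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
    xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  } else xp <- x
  idx <- convIndices(d[1], d[2], d[3], k)
  # index with a plain vector: a matrix subscript whose column count
  # happens to equal the array rank would be read as coordinates
  X2 <- xp[as.vector(idx)]; dim(X2) <- dim(idx)
  list(Y = X2 %*% matrix(W, k * k * d[3], dim(W)[4]), X2 = X2)
}

## --- node constructors ------------------------------------------------------

nnConv <- function(inC, outC, k = 3, init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "zero") array(0, c(k, k, inC, outC))
  else array(stats::rnorm(k * k * inC * outC, sd = sqrt(2 / (k * k * inC))),
             c(k, k, inC, outC))
  list(type = "conv", W = W, b = numeric(outC), k = k, inC = inC, outC = outC)
}

nnDense <- function(inN, outN, init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "zero") matrix(0, inN, outN)
  else matrix(stats::rnorm(inN * outN, sd = sqrt(2 / inN)), inN, outN)
  list(type = "dense", W = W, b = numeric(outN))
}

nnRelu <- function() list(type = "relu")
nnSigmoid <- function() list(type = "sigmoid")
nnPool <- function(f) list(type = "pool", f = as.integer(f))
nnUpsample <- function(f) list(type = "upsample", f = as.integer(f))
nnGap <- function() list(type = "gap")
nnDropout <- function(p) list(type = "dropout", p = p)
nnSeq <- function(...) list(type = "seq", children = list(...))

#' Residual block
#'
#' Composite node computing y = F(x) + shortcut(x). With an identity
#' shortcut and all convolution weights zero the block is exactly the
#' identity map. A 1x1 convolution shortcut is inserted automatically when
#' the channel count changes.
#'
#' @param inC,outC channel counts
#' @param k kernel size
#' @param init "he" (random) or "zero"
#' @return a network node usable with [nnForward()].
#' @export
residualBlock <- function(inC, outC, k = 3, init = "he") {
  body <- nnSeq(nnConv(inC, outC, k, init), nnRelu(),
                nnConv(outC, outC, k, init))
  shortcut <- if (inC == outC) NULL else nnConv(inC, outC, 1, init)
  list(type = "residual", body = body, shortcut = shortcut)
}

#' Attention module
#'
#' Attention-residual composite y = (1 + M(x)) * T(x): the trunk branch T is
#' a residual block and the mask branch M is a sigmoid-terminated
#' encoder-decoder (downsample, convolutions, upsample), so M is strictly
#' inside (0, 1) and the trunk information is preserved.
#'
#' @param channels trunk channel count
#' @param init "he" or "zero"
#' @return a network node usable with [nnForward()].
#' @export
attentionModule <- function(channels, init = "he") {
  trunk <- residualBlock(channels, channels, init = init)
  mask <- nnSeq(nnPool(2), nnConv(channels, channels, 3, init), nnRelu(),
                nnConv(channels, channels, 3, init), nnUpsample(2),
                nnSigmoid())
  list(type = "attention", trunk = trunk, mask = mask)
}

## --- forward / backward -----------------------------------------------------

poolArray <- function(x, f) {
  d <- dim(x)
  if (f == 1L) return(x)
  if (d[1] %% f != 0 || d[2] %% f != 0) stop("pool factor must divide dims")
  m <- colMeans(array(x, c(f, d[1] / f, d[2] * d[3])))
  m <- array(m, c(d[1] / f, d[2], d[3]))
  m <- aperm(m, c(2, 1, 3))
  m <- colMeans(array(m, c(f, d[2] / f, d[1] / f * d[3])))
  aperm(array(m, c(d[2] / f, d[1] / f, d[3])), c(2, 1, 3))
}

upsampleArray <- function(x, f) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), ,
    drop = FALSE]
}

softmaxVec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Forward pass through a network node
#'
#' @param node a node (see [residualBlock()], [attentionModule()])
#' @param x input: numeric array [H, W, C] or numeric vector
#' @param train TRUE enables dropout sampling
#' @return the output activation.
#' @export
nnForward <- function(node, x, train = FALSE) nnForwardC(node, x, train)$y

# forward with caches, internal
nnForwardC <- function(node, x, train = FALSE) {
  switch(node$type,
    conv = {
      d <- dim(x)
      if (length(d) != 3L || d[3] != node$inC)
        stop("conv input shape mismatch")
      r <- convSame(x, node$W)
      Y <- r$Y + rep(node$b, each = nrow(r$Y))
      list(y = array(Y, c(d[1], d[2], node$outC)),
           cache = list(X2 = r$X2, d = d))
    },
    dense = {
      if (length(x) != nrow(node$W)) stop("dense input length mismatch")
      list(y = drop(x %*% node$W) + node$b, cache = list(x = x))
    },
    relu = list(y = pmax(x, 0), cache = list(pos = x > 0)),
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = list(y = y))
    },
    pool = list(y = poolArray(x, node$f), cache = list(d = dim(x))),
    upsample = list(y = upsampleArray(x, node$f), cache = list(d = dim(x))),
    gap = {
      d <- dim(x)
      list(y = colMeans(matrix(x, d[1] * d[2], d[3])), cache = list(d = d))
    },
    dropout = {
      if (!train || node$p <= 0)
        list(y = x, cache = list(mask = NULL))
      else {
        mask <- (stats::runif(length(x)) > node$p) / (1 - node$p)
        if (!is.null(dim(x))) dim(mask) <- dim(x)
        list(y = x * mask, cache = list(mask = mask))
      }
    },
    seq = {
      caches <- vector("list", length(node$children))
      for (i in seq_along(node$children)) {
        r <- nnForwardC(node$children[[i]], x, train)
        x <- r$y; caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    residual = {
      rb <- nnForwardC(node$body, x, train)
      rs <- if (is.null(node$shortcut)) NULL
      else nnForwardC(node$shortcut, x, train)
      ys <- if (is.null(rs)) x else rs$y
      if (!identical(dim(rb$y), dim(ys)))
        stop("shape mismatch between residual branches")
      list(y = rb$y + ys,
           cache = list(body = rb$cache,
                        shortcut = if (is.null(rs)) NULL else rs$cache,
                        x = x))
    },
    attention = {
      rt <- nnForwardC(node$trunk, x, train)
      rm <- nnForwardC(node$mask, x, train)
      if (!identical(dim(rt$y), dim(rm$y)))
        stop("shape mismatch between mask and trunk branches")
      list(y = (1 + rm$y) * rt$y,
           cache = list(trunk = rt$cache, mask = rm$cache,
                        T = rt$y, M = rm$y)) },
    stop("unknown node type ", node$type))
}

# backward pass: returns list(dx, grads); grads mirrors the param tree
nnBackwardC <- function(node, cache, dy) {
  switch(node$type,
    conv = {
      d <- cache$d; k <- node$k
      dY <- matrix(dy, d[1] * d[2], node$outC)
      dW <- crossprod(cache$X2, dY)
      db <- colSums(dY)
      # input gradient of a stride-1 same-conv = same-conv of dY with the
      # spatially flipped kernel and in/out channels swapped
      Wf <- aperm(node$W[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
      dyArr <- array(dy, c(d[1], d[2], node$outC))
      dx <- array(convSame(dyArr, Wf)$Y, c(d[1], d[2], node$inC))
      list(dx = dx, grads = list(W = array(dW, dim(node$W)), b = db))
    },
    dense = list(dx = drop(node$W %*% dy),
                 grads = list(W = outer(cache$x, dy), b = dy)),
    relu = list(dx = dy * cache$pos, grads = NULL),
    sigmoid = list(dx = dy * cache$y * (1 - cache$y), grads = NULL),
    pool = {
      f <- node$f; d <- cache$d
      dyv <- dy / f^2
      list(dx = dyv[rep(seq_len(d[1] / f), each = f),
                    rep(seq_len(d[2] / f), each = f), , drop = FALSE],
           grads = NULL)
    },
    upsample = {
      f <- node$f
      list(dx = poolArray(dy, f) * f^2, grads = NULL)
    },
    gap = {
      d <- cache$d
      list(dx = array(rep(dy, each = d[1] * d[2]) / (d[1] * d[2]), d),
           grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    },
    seq = {
      n <- length(node$children)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        r <- nnBackwardC(node$children[[i]], cache[[i]], dy)
        dy <- r$dx; grads[[i]] <- r$grads
      }
      list(dx = dy, grads = grads)
    },
    residual = {
      rb <- nnBackwardC(node$body, cache$body, dy)
      if (is.null(node$shortcut))
        list(dx = rb$dx + dy, grads = list(body = rb$grads, shortcut = NULL))
      else {
        rs <- nnBackwardC(node$shortcut, cache$shortcut, dy)
        list(dx = rb$dx + rs$dx,
             grads = list(body = rb$grads, shortcut = rs$grads))
      }
    },
    attention = {
      rt <- nnBackwardC(node$trunk, cache$trunk, dy * (1 + cache$M))
      rm <- nnBackwardC(node$mask, cache$mask, dy * cache$T)
      list(dx = rt$dx + rm$dx,
           grads = list(trunk = rt$grads, mask = rm$grads))
    },
    stop("unknown node type ", node$type))
}

#' Gradient of a node with respect to its input and parameters
#'
#' Runs one forward/backward pass; mainly useful for inspection and testing.
#'
#' @param node a network node
#' @param x input
#' @param dy upstream gradient (same shape as the node output)
#' @return list(dx, grads)
#' @export
nnGrad <- function(node, x, dy) {
  r <- nnForwardC(node, x, train = FALSE)
  nnBackwardC(node, r$cache, dy)
}

## --- parameter tree utilities ----------------------------------------------

nodeParams <- function(node) {
  switch(node$type,
    conv = list(W = node$W, b = node$b),
    dense = list(W = node$W, b = node$b),
    seq = lapply(node$children, nodeParams),
    residual = list(body = nodeParams(node$body),
                    shortcut = if (is.null(node$shortcut)) NULL
                    else nodeParams(node$shortcut)),
    attention = list(trunk = nodeParams(node$trunk),
                     mask = nodeParams(node$mask)),
    NULL)
}

flattenParams <- function(p) {
  out <- list()
  rec <- function(x) {
    if (is.null(x)) return(invisible())
    if (is.numeric(x)) { out[[length(out) + 1]] <<- x; return(invisible()) }
    for (el in x) rec(el)
  }
  rec(p)
  out
}

setNodeParams <- function(node, flat, counter = new.env()) {
  if (is.null(counter$i)) counter$i <- 0L
  takeNext <- function() {
    counter$i <- counter$i + 1L
    flat[[counter$i]]
  }
  switch(node$type,
    conv = { node$W <- array(takeNext(), dim(node$W))
             node$b <- as.numeric(takeNext()); node },
    dense = { node$W <- matrix(takeNext(), nrow(node$W), ncol(node$W))
              node$b <- as.numeric(takeNext()); node },
    seq = { node$children <- lapply(node$children, setNodeParams, flat = flat,
                                    counter = counter); node },
    residual = { node$body <- setNodeParams(node$body, flat, counter)
                 if (!is.null(node$shortcut))
                   node$shortcut <- setNodeParams(node$shortcut, flat, counter)
                 node },
    attention = { node$trunk <- setNodeParams(node$trunk, flat, counter)
                  node$mask <- setNodeParams(node$mask, flat, counter)
                  node },
    node)
}

zeroNodeParams <- function(node) {
  flat <- flattenParams(nodeParams(node))
  setNodeParams(node, lapply(flat, function(x) x * 0))
}

## --- loss and optimizer -----------------------------------------------------

# class-weighted softmax cross-entropy on 2-class logits.
# loss contribution is weight * (-log p[label]); gradient matches.
weightedCELoss <- function(logits, labelIdx, weight) {
  p <- softmaxVec(logits)
  grad <- p
  grad[labelIdx] <- grad[labelIdx] - 1
  list(loss = -weight * log(max(p[labelIdx], 1e-12)), dlogits = weight * grad)
}

adamInit <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mh <- state$m[[i]] / (1 - beta1^state$t)
    vh <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

addFlat <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(a)) a[[i]] <- a[[i]] + b[[i]]
  a
}
scaleFlat <- function(a, s) lapply(a, function(x) x * s)

## --- generic training loop --------------------------------------------------

# train a full network (single node tree) with Adam, class-weighted CE,
# optional per-sample augmentation and early stopping on validation loss.
# labels are "responder"/"non-responder"; the non-responder class carries
# weight `classWeight`.
trainNet <- function(node, xs, labels, valXs = NULL, valLabels = NULL,
                     cfg, augment = NULL) {
  labels <- assertLabels(labels)
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  n <- length(xs)
  yIdx <- match(labels, responseLevels)
  wts <- ifelse(yIdx == 2L, cfg$classWeight, 1)
  hasVal <- !is.null(valXs) && length(valXs) > 0
  if (hasVal) {
    valLabels <- assertLabels(valLabels)
    vIdx <- match(valLabels, responseLevels)
    vW <- ifelse(vIdx == 2L, cfg$classWeight, 1)
  }
  params <- flattenParams(nodeParams(node))
  opt <- adamInit(params)
  bestLoss <- Inf; bestParams <- params; wait <- 0L
  hist <- data.frame()
  evalSet <- function(xl, yi, wv) {
    loss <- 0; acc <- 0
    for (i in seq_along(xl)) {
      logits <- nnForwardC(node, xl[[i]], train = FALSE)$y
      loss <- loss + weightedCELoss(logits, yi[i], wv[i])$loss
      acc <- acc + (which.max(logits) == yi[i])
    }
    c(loss / length(xl), acc / length(xl))
  }
  for (epoch in seq_len(cfg$maxEpochs)) {
    ord <- sample.int(n)
    epochLoss <- 0
    for (b0 in seq(1, n, by = cfg$batchSize)) {
      batch <- ord[b0:min(b0 + cfg$batchSize - 1, n)]
      gacc <- NULL
      for (i in batch) {
        x <- if (is.null(augment)) xs[[i]] else augment(xs[[i]])
        fw <- nnForwardC(node, x, train = TRUE)
        lo <- weightedCELoss(fw$y, yIdx[i], wts[i])
        epochLoss <- epochLoss + lo$loss
        bk <- nnBackwardC(node, fw$cache, lo$dlogits)
        gacc <- addFlat(gacc, flattenParams(bk$grads))
      }
      st <- adamStep(params, scaleFlat(gacc, 1 / length(batch)), opt,
                     cfg$learningRate)
      params <- st$params; opt <- st$state
      node <- setNodeParams(node, params)
    }
    row <- data.frame(epoch = epoch, trainLoss = epochLoss / n,
                      valLoss = NA_real_, valAcc = NA_real_)
    if (hasVal) {
      ev <- evalSet(valXs, vIdx, vW)
      row$valLoss <- ev[1]; row$valAcc <- ev[2]
      if (ev[1] < bestLoss - 1e-9) {
        bestLoss <- ev[1]; bestParams <- params; wait <- 0L
      } else wait <- wait + 1L
      hist <- rbind(hist, row)
      if (wait >= cfg$patience) break
    } else hist <- rbind(hist, row)
  }
  if (hasVal) node <- setNodeParams(node, bestParams)
  list(node = node, history = hist)
}

# stochastic horizontal flip and zero-filled lateral/axial shift
augmentImage <- function(x, hflip, shiftMaxFraction) {
  d <- dim(x)
  if (hflip && stats::runif(1) < 0.5) x <- x[, d[2]:1, , drop = FALSE]
  s <- floor(shiftMaxFraction * d[1])
  if (s > 0) {
    dr <- sample(-s:s, 1); dc <- sample(-s:s, 1)
    if (dr != 0 || dc != 0) {
      y <- array(0, d)
      srcR <- max(1, 1 - dr):min(d[1], d[1] - dr)
      srcC <- max(1, 1 - dc):min(d[2], d[2] - dc)
      y[srcR + dr, srcC + dc, ] <- x[srcR, srcC, , drop = FALSE]
      x <- y
    }
  }
  x
}
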
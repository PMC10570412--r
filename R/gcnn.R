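# Chebyshev graph convolutional classifier.
#
# Two graph-convolution blocks (conv -> max-pool -> ReLU), two fully
# connected layers with an intermediate ReLU + dropout, and a softmax
# output. Filters are Chebyshev polynomials T_k of the rescaled graph
# Laplacian, applied along the node axis independently for each position
# on the feature axis, with weights shared across feature positions.
# Forward, backward and the SGD-with-momentum loop are implemented here in
# plain array arithmetic; the network is small (about 1,500 parameters).

#' Rescaled graph Laplacian
#'
#' \code{Ltilde = 2 * Lnorm / lambda_max - I} with
#' \code{Lnorm = I - D^(-1/2) A D^(-1/2)}; \code{lambda_max} is computed
#' numerically, putting the spectrum in [-1, 1]. A zero-degree node has
#' its degree treated as 1 with a warning.
#'
#' @param adjacency symmetric non-negative adjacency matrix.
#' @return The rescaled Laplacian matrix.
#' @export
scaledLaplacian <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A) || !isTRUE(all.equal(A, t(A))) || any(A < 0))
    stop("adjacency must be square, symmetric and non-negative")
  d <- rowSums(A)
  dd <- d
  if (any(d == 0)) {
    warning("isolated node(s): degree treated as 1")
    dd[d == 0] <- 1
  }
  dm <- 1 / sqrt(dd)
  # D^{-1/2} (D - A) D^{-1/2}; isolated nodes keep an all-zero row
  L <- diag(d, nrow = length(d)) - A
  Ln <- (dm * L) * rep(dm, each = nrow(A))
  Ln <- (Ln + t(Ln)) / 2
  lmax <- max(eigen(Ln, symmetric = TRUE, only.values = TRUE)$values)
  if (lmax < 1e-12) lmax <- 2  # empty graph: Ln = 0, Ltilde = -I
  2 * Ln / lmax - diag(nrow(A))
}

# Chebyshev basis T_0..T_{K-1} of a rescaled Laplacian, via the recurrence
# T_k = 2 L T_{k-1} - T_{k-2}
chebBasis <- function(Lt, K) {
  Tk <- vector("list", K)
  Tk[[1]] <- diag(nrow(Lt))
  if (K >= 2) Tk[[2]] <- Lt
  if (K >= 3) for (k in 3:K) Tk[[k]] <- 2 * Lt %*% Tk[[k - 1]] - Tk[[k - 2]]
  Tk
}

#' Model architecture configuration
#'
#' Defaults reproduce the printed two-block architecture: blocks of 10 and
#' 20 channels, nodes pooled 8 -> 4 -> 2 and features 5 -> 3 -> 1 (so the
#' flatten width is 20 * 2 * 1 = 40), a 15-unit hidden FC layer and 3
#' output classes.
#'
#' @param nNodes,inFeatureLen input graph size (8 nodes x 5 features).
#' @param blockChannels output channels of the two convolution blocks.
#' @param chebOrder Chebyshev polynomial order K.
#' @param fcHidden hidden fully-connected width.
#' @param nClasses number of classes.
#' @param dropoutRate dropout probability between the FC layers.
#' @param pooledNodes,pooledFeatures node/feature axis sizes after each
#'   block's max-pooling.
#' @export
gcnnConfig <- function(nNodes = 8, inFeatureLen = 5,
                       blockChannels = c(10, 20), chebOrder = 3,
                       fcHidden = 15, nClasses = 3, dropoutRate = 0.5,
                       pooledNodes = c(4, 2), pooledFeatures = c(3, 1)) {
  flatten <- blockChannels[2] * pooledNodes[2] * pooledFeatures[2]
  cfg <- list(nNodes = nNodes, inFeatureLen = inFeatureLen,
              blockChannels = blockChannels, chebOrder = chebOrder,
              fcHidden = fcHidden, nClasses = nClasses,
              dropoutRate = dropoutRate, pooledNodes = pooledNodes,
              pooledFeatures = pooledFeatures, flattenWidth = flatten)
  stopifnot(chebOrder >= 1, all(pooledNodes >= 1), dropoutRate >= 0,
            dropoutRate < 1)
  cfg
}

#' Training hyperparameters
#'
#' Defaults follow the published settings: learning rate 0.001, momentum
#' 0.5, training batch size 6, cross-entropy loss, progress logged every
#' 10 batches. The published epoch counts are 3 when fitting an individual
#' subject and 50 across subjects; 50 is the package default for a single
#' run and both are used by [runPerSubject()].
#'
#' @param learning_rate SGD step size.
#' @param epochs passes over the training set.
#' @param batch_size_train mini-batch size.
#' @param momentum SGD momentum coefficient.
#' @param log_interval batches between progress log lines.
#' @param seed seed for weight init, shuffling and dropout.
#' @export
trainConfig <- function(learning_rate = 0.001, epochs = 50,
                        batch_size_train = 6, momentum = 0.5,
                        log_interval = 10, seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size_train >= 1,
            momentum >= 0, log_interval >= 1)
  list(learning_rate = learning_rate, epochs = as.integer(epochs),
       batch_size_train = as.integer(batch_size_train),
       momentum = momentum, log_interval = as.integer(log_interval),
       seed = as.integer(seed))
}

# complete graph with unit edges, no self-loops
completeAdjacency <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0
  A
}

#' Initialise an untrained model
#'
#' Weights are seeded uniform with ReLU-gain fan-in scaling
#' (\code{U(-sqrt(2/fanin), sqrt(2/fanin))}) for determinism. The block-2
#' graph is the complete graph on the pooled nodes (coarsening a uniform
#' complete graph is degenerate: every pairing is equivalent).
#'
#' @param mcfg a [gcnnConfig()].
#' @param seed weight-initialisation seed.
#' @param adjacency input graph adjacency (default: complete graph).
#' @return An untrained [GCNNModel-class].
#' @export
initGCNN <- function(mcfg = gcnnConfig(), seed = 1,
                     adjacency = completeAdjacency(mcfg$nNodes)) {
  K <- mcfg$chebOrder
  Tk1 <- chebBasis(scaledLaplacian(adjacency), K)
  Tk2 <- chebBasis(scaledLaplacian(completeAdjacency(mcfg$pooledNodes[1])), K)
  uinit <- function(dims, fanin)
    array(stats::runif(prod(dims), -sqrt(2 / fanin), sqrt(2 / fanin)), dims)
  w <- withr::with_seed(deriveSeed(seed, 1L), list(
    W1 = uinit(c(K, 1, mcfg$blockChannels[1]), K * 1),
    b1 = rep(0, mcfg$blockChannels[1]),
    W2 = uinit(c(K, mcfg$blockChannels[1], mcfg$blockChannels[2]),
               K * mcfg$blockChannels[1]),
    b2 = rep(0, mcfg$blockChannels[2]),
    Wf1 = uinit(c(mcfg$flattenWidth, mcfg$fcHidden), mcfg$flattenWidth),
    bf1 = rep(0, mcfg$fcHidden),
    Wf2 = uinit(c(mcfg$fcHidden, mcfg$nClasses), mcfg$fcHidden),
    bf2 = rep(0, mcfg$nClasses)))
  new("GCNNModel", config = mcfg, weights = w,
      laplacians = list(Tk1 = Tk1, Tk2 = Tk2), trained = FALSE)
}

# ---- layer forward/backward ------------------------------------------------

chebConvForward <- function(x, Tks, W, b) {
  d <- dim(x); B <- d[1]; C <- d[2]; N <- d[3]; F_ <- d[4]
  K <- length(Tks); O <- dim(W)[3]
  M <- matrix(0, B * N * F_, K * C)
  for (k in seq_len(K)) {
    xm <- matrix(aperm(x, c(3, 1, 2, 4)), N, B * C * F_)
    zk <- array(Tks[[k]] %*% xm, c(N, B, C, F_))
    M[, k + K * (seq_len(C) - 1L)] <-
      matrix(aperm(zk, c(2, 1, 4, 3)), B * N * F_, C)
  }
  Wm <- matrix(W, K * C, O)
  Y <- M %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  y <- aperm(array(Y, c(B, N, F_, O)), c(1, 4, 2, 3))
  list(out = y, cache = list(M = M, Wm = Wm, dims = d, K = K, Tks = Tks))
}

chebConvBackward <- function(dy, cache) {
  d <- cache$dims; B <- d[1]; C <- d[2]; N <- d[3]; F_ <- d[4]
  K <- cache$K; O <- ncol(cache$Wm)
  dYm <- matrix(aperm(dy, c(1, 3, 4, 2)), B * N * F_, O)
  dW <- array(crossprod(cache$M, dYm), c(K, C, O))
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, cache$Wm)
  dx <- array(0, d)
  for (k in seq_len(K)) {
    dzk <- array(dM[, k + K * (seq_len(C) - 1L)], c(B, N, F_, C))
    dzm <- matrix(aperm(dzk, c(2, 1, 4, 3)), N, B * C * F_)
    back <- array(t(cache$Tks[[k]]) %*% dzm, c(N, B, C, F_))
    dx <- dx + aperm(back, c(2, 3, 1, 4))
  }
  list(dx = dx, dW = dW, db = db)
}

# left-aligned windows of width floor(L/target); the last window absorbs
# the remainder. Node pooling (8 -> 4, 4 -> 2) and feature pooling
# (5 -> 3, 3 -> 1) both use this rule.
poolWindows <- function(L, target) {
  w <- L %/% target
  starts <- (seq_len(target) - 1L) * w + 1L
  ends <- c(starts[-1L] - 1L, L)
  Map(function(s, e) s:e, starts, ends)
}

poolAxisForward <- function(x, axis, target) {
  d <- dim(x)
  wins <- poolWindows(d[axis], target)
  dOut <- d; dOut[axis] <- target
  out <- array(-Inf, dOut)
  arg <- array(0L, dOut)
  slab <- function(a, i) {
    idx <- list(TRUE, TRUE, TRUE, TRUE); idx[[axis]] <- i
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  for (wi in seq_along(wins)) {
    for (p in wins[[wi]]) {
      v <- slab(x, p)
      cur <- slab(out, wi)
      upd <- v > cur
      cur[upd] <- v[upd]
      ca <- slab(arg, wi)
      ca[upd] <- p
      idx <- list(TRUE, TRUE, TRUE, TRUE); idx[[axis]] <- wi
      out <- do.call(`[<-`, c(list(out), idx, list(cur)))
      arg <- do.call(`[<-`, c(list(arg), idx, list(ca)))
    }
  }
  list(out = out, arg = arg, wins = wins, axis = axis, inDim = d)
}

poolAxisBackward <- function(dOut, cache) {
  dx <- array(0, cache$inDim)
  axis <- cache$axis
  slab <- function(a, i) {
    idx <- list(TRUE, TRUE, TRUE, TRUE); idx[[axis]] <- i
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  for (wi in seq_along(cache$wins)) {
    g <- slab(dOut, wi)
    a <- slab(cache$arg, wi)
    for (p in cache$wins[[wi]]) {
      contrib <- g * (a == p)
      idx <- list(TRUE, TRUE, TRUE, TRUE); idx[[axis]] <- p
      cur <- slab(dx, p) + contrib
      dx <- do.call(`[<-`, c(list(dx), idx, list(cur)))
    }
  }
  dx
}

#' Max-pool one convolution block's output
#'
#' Pools the node axis over fixed adjacent pairs and the feature axis onto
#' the configured target length. Exposed mainly for shape verification.
#'
#' @param x array \code{[batch, channels, nodes, features]} with an even
#'   node count.
#' @param targetNodes,targetFeatures output axis lengths.
#' @return The pooled array.
#' @export
poolBlock <- function(x, targetNodes, targetFeatures) {
  if (dim(x)[3] %% 2L != 0L) stop("node axis length must be even")
  p1 <- poolAxisForward(x, 3L, targetNodes)
  p2 <- poolAxisForward(p1$out, 4L, targetFeatures)
  p2$out
}

#' Chebyshev graph convolution
#'
#' \code{y = sum_k T_k(Ltilde) x W_k} along the node axis, weights shared
#' across feature-axis positions. Exposed for testing against a direct
#' polynomial expansion.
#'
#' @param x array \code{[batch, in_channels, nodes, features]}.
#' @param Lt rescaled Laplacian matching the node count.
#' @param W weight array \code{[K, in_channels, out_channels]}.
#' @param b per-output-channel bias (default zeros).
#' @return Array \code{[batch, out_channels, nodes, features]}.
#' @export
chebConv <- function(x, Lt, W, b = rep(0, dim(W)[3])) {
  if (dim(x)[2] != dim(W)[2])
    stop("input channel count does not match the weight array")
  if (nrow(Lt) != dim(x)[3])
    stop("Laplacian size does not match the node axis")
  chebConvForward(x, chebBasis(Lt, dim(W)[1]), W, b)$out
}

# full forward pass; returns caches when training = TRUE
gcnnForwardFull <- function(model, x, training = FALSE, dropMask = NULL) {
  cfg <- model@config; w <- model@weights
  shapes <- list(input = dim(x))
  c1 <- chebConvForward(x, model@laplacians$Tk1, w$W1, w$b1)
  p1a <- poolAxisForward(c1$out, 3L, cfg$pooledNodes[1])
  p1b <- poolAxisForward(p1a$out, 4L, cfg$pooledFeatures[1])
  r1 <- pmax(p1b$out, 0)
  shapes$block1 <- dim(r1)
  c2 <- chebConvForward(r1, model@laplacians$Tk2, w$W2, w$b2)
  p2a <- poolAxisForward(c2$out, 3L, cfg$pooledNodes[2])
  p2b <- poolAxisForward(p2a$out, 4L, cfg$pooledFeatures[2])
  r2 <- pmax(p2b$out, 0)
  shapes$block2 <- dim(r2)
  B <- dim(x)[1]
  flat <- t(matrix(aperm(r2, c(2, 3, 4, 1)), cfg$flattenWidth, B))
  shapes$flatten <- dim(flat)
  h <- flat %*% w$Wf1 + rep(w$bf1, each = B)
  hr <- pmax(h, 0)
  shapes$fc1 <- dim(hr)
  if (training && cfg$dropoutRate > 0) {
    if (is.null(dropMask))
      dropMask <- matrix(stats::rbinom(length(hr), 1, 1 - cfg$dropoutRate),
                         nrow(hr), ncol(hr)) / (1 - cfg$dropoutRate)
    hd <- hr * dropMask
  } else {
    dropMask <- NULL
    hd <- hr
  }
  logits <- hd %*% w$Wf2 + rep(w$bf2, each = B)
  shapes$output <- dim(logits)
  lmax <- apply(logits, 1, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  list(probs = probs, logits = logits, shapes = shapes,
       cache = list(c1 = c1, p1a = p1a, p1b = p1b, r1 = r1,
                    c2 = c2, p2a = p2a, p2b = p2b, r2 = r2,
                    flat = flat, h = h, hr = hr, hd = hd,
                    dropMask = dropMask, B = B))
}

#' Forward pass of the classifier
#'
#' @param model a [GCNNModel-class].
#' @param x input array \code{[batch, 1, nodes, features]}.
#' @param training apply dropout (TRUE) or run deterministically (FALSE).
#' @return Matrix \code{[batch, nClasses]} of class probabilities (rows
#'   sum to 1). The per-layer output shapes are attached as attribute
#'   \code{"shapes"}.
#' @export
gcnnForward <- function(model, x, training = FALSE) {
  if (length(dim(x)) != 4L || dim(x)[2] != 1L ||
      dim(x)[3] != model@config$nNodes ||
      dim(x)[4] != model@config$inFeatureLen)
    stop("input must be [batch, 1, ", model@config$nNodes, ", ",
         model@config$inFeatureLen, "]")
  fw <- gcnnForwardFull(model, x, training = training)
  structure(fw$probs, shapes = fw$shapes)
}

# cross-entropy loss and full gradient for one batch
gcnnLossGrad <- function(model, x, labels, dropMask = NULL) {
  fw <- gcnnForwardFull(model, x, training = TRUE, dropMask = dropMask)
  cfg <- model@config; w <- model@weights; cc <- fw$cache
  B <- cc$B
  Y <- matrix(0, B, cfg$nClasses)
  Y[cbind(seq_len(B), labels + 1L)] <- 1
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(B), labels + 1L)], 1e-300)))
  dlogits <- (fw$probs - Y) / B
  gWf2 <- crossprod(cc$hd, dlogits)
  gbf2 <- colSums(dlogits)
  dhd <- tcrossprod(dlogits, w$Wf2)
  dhr <- if (is.null(cc$dropMask)) dhd else dhd * cc$dropMask
  dh <- dhr * (cc$h > 0)
  gWf1 <- crossprod(cc$flat, dh)
  gbf1 <- colSums(dh)
  dflat <- tcrossprod(dh, w$Wf1)
  dr2 <- aperm(array(t(dflat), c(dim(cc$r2)[2], dim(cc$r2)[3],
                                 dim(cc$r2)[4], B)), c(4, 1, 2, 3))
  dp2b <- dr2 * (cc$p2b$out > 0)
  dp2a <- poolAxisBackward(dp2b, cc$p2b)
  dc2 <- poolAxisBackward(dp2a, cc$p2a)
  bk2 <- chebConvBackward(dc2, cc$c2$cache)
  dr1 <- bk2$dx * (cc$p1b$out > 0)
  dp1a <- poolAxisBackward(dr1, cc$p1b)
  dc1 <- poolAxisBackward(dp1a, cc$p1a)
  bk1 <- chebConvBackward(dc1, cc$c1$cache)
  list(loss = loss,
       grads = list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
                    Wf1 = gWf1, bf1 = gbf1, Wf2 = gWf2, bf2 = gbf2))
}

samplesToArray <- function(samples) {
  B <- length(samples)
  n <- nrow(samples[[1]]@nodeFeatures); f <- ncol(samples[[1]]@nodeFeatures)
  x <- array(0, c(B, 1, n, f))
  for (i in seq_len(B)) x[i, 1, , ] <- samples[[i]]@nodeFeatures
  x
}

sampleLabels <- function(samples)
  vapply(samples, function(s) s@label, integer(1))

#' Train the classifier
#'
#' Mini-batch stochastic gradient descent with momentum on the
#' cross-entropy loss. The validation set is scored after every epoch and
#' the weights with the best validation accuracy are returned. Fully
#' deterministic for fixed seeds (single-threaded array arithmetic).
#'
#' @param split a [DatasetSplit-class] with non-empty train and validation
#'   sets (standardise first with [standardizeFeatures()]).
#' @param mcfg a [gcnnConfig()].
#' @param tcfg a [trainConfig()].
#' @param verbose log every \code{log_interval} batches.
#' @return A list: \code{model} (trained [GCNNModel-class]) and
#'   \code{history} (data.frame of per-epoch train loss, validation loss
#'   and validation accuracy).
#' @export
trainModel <- function(split, mcfg = gcnnConfig(), tcfg = trainConfig(),
                       verbose = FALSE) {
  if (!length(split@train) || !length(split@validation))
    stop("train and validation sets must be non-empty")
  model <- initGCNN(mcfg, seed = tcfg$seed)
  xTr <- samplesToArray(split@train); yTr <- sampleLabels(split@train)
  xVa <- samplesToArray(split@validation); yVa <- sampleLabels(split@validation)
  nTr <- length(yTr)
  vel <- lapply(model@weights, function(w) w * 0)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric())
  best <- list(acc = -1, weights = model@weights)
  for (ep in seq_len(tcfg$epochs)) {
    perm <- withr::with_seed(deriveSeed(tcfg$seed, 100L + ep), sample(nTr))
    nBatch <- ceiling(nTr / tcfg$batch_size_train)
    epLoss <- 0
    rngSeed <- deriveSeed(tcfg$seed, 10000L + ep)
    withr::with_seed(rngSeed, {
      for (b in seq_len(nBatch)) {
        idx <- perm[((b - 1L) * tcfg$batch_size_train + 1L):
                      min(b * tcfg$batch_size_train, nTr)]
        lg <- gcnnLossGrad(model, xTr[idx, , , , drop = FALSE], yTr[idx])
        if (!is.finite(lg$loss))
          stop(sprintf("non-finite loss at epoch %d batch %d; aborting",
                       ep, b))
        for (nm in names(model@weights)) {
          vel[[nm]] <- tcfg$momentum * vel[[nm]] -
            tcfg$learning_rate * lg$grads[[nm]]
          model@weights[[nm]] <- model@weights[[nm]] + vel[[nm]]
        }
        epLoss <- epLoss + lg$loss * length(idx)
        if (verbose && b %% tcfg$log_interval == 0L)
          message(sprintf("epoch %d batch %d/%d loss %.4f",
                          ep, b, nBatch, lg$loss))
      }
    })
    pv <- gcnnForwardFull(model, xVa, training = FALSE)
    vaLoss <- -mean(log(pmax(
      pv$probs[cbind(seq_along(yVa), yVa + 1L)], 1e-300)))
    vaAcc <- mean(max.col(pv$probs) - 1L == yVa)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = epLoss / nTr,
                                   val_loss = vaLoss, val_accuracy = vaAcc))
    if (vaAcc > best$acc) best <- list(acc = vaAcc, weights = model@weights)
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f, val loss %.4f, val acc %.4f",
                      ep, epLoss / nTr, vaLoss, vaAcc))
  }
  model@weights <- best$weights
  model@trained <- TRUE
  # carry the split's standardisation so saved models can score raw features
  if (length(split@featureMeans)) {
    model@config$featureMeans <- split@featureMeans
    model@config$featureSds <- split@featureSds
  }
  list(model = model, history = hist)
}

#' Predict stages for graph samples
#'
#' Deterministic inference (dropout disabled); the whole sample list is
#' evaluated in one batch regardless of its size.
#'
#' @param model a trained [GCNNModel-class].
#' @param samples list of [GraphSample-class] objects (standardised with
#'   the training statistics).
#' @return A list with \code{labels} (class indices 0..2) and
#'   \code{probs} (matrix of class probabilities).
#' @export
predictStages <- function(model, samples) {
  if (!model@trained) stop("model has not been trained")
  probs <- gcnnForward(model, samplesToArray(samples), training = FALSE)
  list(labels = max.col(probs) - 1L, probs = unclass(probs))
}

#' Save / load model weights as a plain-text key-value archive
#'
#' @param model a [GCNNModel-class].
#' @param path output file.
#' @export
saveModelWeights <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  extra <- list()
  if (!is.null(model@config$featureMeans)) {
    extra <- list(meta.featureMeans = model@config$featureMeans,
                  meta.featureSds = model@config$featureSds)
  }
  entries <- c(model@weights, extra)
  for (nm in names(entries)) {
    w <- entries[[nm]]
    cat(sprintf("%s dim=%s values=%s\n", nm,
                paste(if (is.null(dim(w))) length(w) else dim(w),
                      collapse = ","),
                paste(sprintf("%.17g", as.numeric(w)), collapse = ",")),
        file = con)
  }
  invisible(path)
}

#' @rdname saveModelWeights
#' @param path weight archive written by [saveModelWeights()].
#' @export
loadModelWeights <- function(model, path) {
  for (ln in readLines(path)) {
    m <- regmatches(ln, regexec("^(\\S+) dim=(\\S+) values=(\\S+)$", ln))[[1]]
    if (length(m) != 4L) stop("malformed weight archive line: ", substr(ln, 1, 40))
    dims <- as.integer(strsplit(m[3], ",")[[1]])
    vals <- as.numeric(strsplit(m[4], ",")[[1]])
    obj <- if (length(dims) > 1L) array(vals, dims) else vals
    if (startsWith(m[2], "meta."))
      model@config[[substring(m[2], 6)]] <- obj
    else
      model@weights[[m[2]]] <- obj
  }
  model@trained <- TRUE
  model
}

#' Apply stored feature standardisation to raw graph samples
#'
#' @param samples list of [GraphSample-class] with raw feature values.
#' @param model a trained [GCNNModel-class] whose config carries the
#'   training-set standardisation parameters.
#' @return The samples with standardised node features.
#' @export
applyStandardization <- function(samples, model) {
  mu <- model@config$featureMeans
  sdv <- model@config$featureSds
  if (is.null(mu)) stop("model carries no standardisation parameters")
  lapply(samples, function(s) {
    s@nodeFeatures <- sweep(sweep(s@nodeFeatures, 2, mu), 2, sdv, "/")
    s
  })
}
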
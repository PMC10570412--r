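# The Chebyshev graph convolutional classifier: spectral construction,
# layer semantics, architecture conformance, gradients and training.

test_that("the K8 normalised Laplacian has the complete-graph spectrum", {
  A <- matrix(1, 8, 8); diag(A) <- 0
  d <- rowSums(A)
  Ln <- diag(8) - diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  ev <- sort(eigen(Ln, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, c(0, rep(8 / 7, 7)), tolerance = 1e-12)  # closed form
  Lt <- scaledLaplacian(A)
  evt <- eigen(Lt, symmetric = TRUE, only.values = TRUE)$values
  expect_lte(max(evt), 1 + 1e-12)
  expect_gte(min(evt), -1 - 1e-12)
  expect_equal(max(evt), 1, tolerance = 1e-12)
})

test_that("degenerate graphs follow the documented conventions", {
  expect_warning(Lt1 <- scaledLaplacian(matrix(0, 1, 1)), "isolated")
  expect_equal(Lt1, -diag(1))
  expect_error(scaledLaplacian(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("Chebyshev convolution reduces correctly in its limiting cases", {
  withr::with_seed(12, {
    x <- array(rnorm(2 * 3 * 4 * 5), c(2, 3, 4, 5))
    Lt <- scaledLaplacian(epistage:::completeAdjacency(4))
    # K = 1: T_0 = I, a per-node linear map with no neighbour mixing
    W1 <- array(rnorm(1 * 3 * 2), c(1, 3, 2))
    y1 <- chebConv(x, Lt, W1)
    manual <- array(0, c(2, 2, 4, 5))
    for (b in 1:2) for (o in 1:2) for (ci in 1:3)
      manual[b, o, , ] <- manual[b, o, , ] + W1[1, ci, o] * x[b, ci, , ]
    expect_equal(y1, manual, tolerance = 1e-12)
    # K = 2 with a zero Laplacian: T_1 term vanishes
    W2 <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
    y2 <- chebConv(x, matrix(0, 4, 4), W2)
    expect_equal(y2, chebConv(x, matrix(0, 4, 4),
                              W2[1, , , drop = FALSE]),
                 tolerance = 1e-12)
    # K = 3 on a 2-node graph: literal polynomial-matrix expansion oracle
    x2 <- array(rnorm(3 * 2 * 2 * 4), c(3, 2, 2, 4))
    Lt2 <- scaledLaplacian(epistage:::completeAdjacency(2))
    W3 <- array(rnorm(3 * 2 * 5), c(3, 2, 5))
    expect_equal(chebConv(x2, Lt2, W3), oracleChebConv(x2, Lt2, W3),
                 tolerance = 1e-10)
  })
})

test_that("pooling reproduces the printed block output sizes", {
  withr::with_seed(13, {
    b1 <- array(rnorm(6 * 10 * 8 * 5), c(6, 10, 8, 5))
    expect_identical(dim(poolBlock(b1, 4, 3)), c(6L, 10L, 4L, 3L))
    b2 <- array(rnorm(6 * 20 * 4 * 3), c(6, 20, 4, 3))
    expect_identical(dim(poolBlock(b2, 2, 1)), c(6L, 20L, 2L, 1L))
    # max-pooling a constant tensor returns the same constant
    cst <- array(3.14, c(2, 3, 8, 5))
    expect_true(all(poolBlock(cst, 4, 3) == 3.14))
    expect_error(poolBlock(array(0, c(1, 1, 7, 5)), 4, 3), "even")
  })
})

test_that("the forward pass conforms to the printed architecture", {
  model <- initGCNN(gcnnConfig(), seed = 3)
  withr::with_seed(14, x <- array(rnorm(6 * 1 * 8 * 5), c(6, 1, 8, 5)))
  probs <- gcnnForward(model, x)
  shp <- attr(probs, "shapes")
  expect_identical(shp$input, c(6L, 1L, 8L, 5L))
  expect_identical(shp$block1, c(6L, 10L, 4L, 3L))
  expect_identical(shp$block2, c(6L, 20L, 2L, 1L))
  expect_identical(shp$flatten, c(6L, 40L))
  expect_identical(shp$fc1, c(6L, 15L))
  expect_identical(shp$output, c(6L, 3L))
  expect_equal(unname(rowSums(probs)), rep(1, 6), tolerance = 1e-6)
  expect_true(all(probs > 0))
  # other batch sizes keep the same layer geometry
  p1 <- gcnnForward(model, x[1, , , , drop = FALSE])
  expect_identical(attr(p1, "shapes")$flatten, c(1L, 40L))
  expect_error(gcnnForward(model, array(0, c(2, 1, 7, 5))), "input must be")
})

test_that("ReLU clamps exactly as defined", {
  expect_equal(pmax(c(-2, 0, 3), 0), c(0, 0, 3))
  # and inside the network: negative pre-activations produce zero blocks
  model <- initGCNN(gcnnConfig(), seed = 5)
  x <- array(0, c(1, 1, 8, 5))
  fw <- epistage:::gcnnForwardFull(model, x)
  expect_true(all(fw$cache$r1 >= 0) && all(fw$cache$r2 >= 0))
})

test_that("backpropagation matches finite-difference gradients", {
  withr::with_seed(15, {
    mcfg <- gcnnConfig()
    model <- initGCNN(mcfg, seed = 2)
    x <- array(rnorm(4 * 1 * 8 * 5), c(4, 1, 8, 5))
    y <- c(0L, 1L, 2L, 1L)
    mask <- matrix(1, 4, mcfg$fcHidden)   # freeze dropout for the check
    lg <- epistage:::gcnnLossGrad(model, x, y, dropMask = mask)
    eps <- 1e-6
    for (nm in names(model@weights)) {
      w <- model@weights[[nm]]
      for (i in sample(length(w), min(2, length(w)))) {
        m2 <- model; m2@weights[[nm]][i] <- w[i] + eps
        lp <- epistage:::gcnnLossGrad(m2, x, y, dropMask = mask)$loss
        m2@weights[[nm]][i] <- w[i] - eps
        lm <- epistage:::gcnnLossGrad(m2, x, y, dropMask = mask)$loss
        fd <- (lp - lm) / (2 * eps)
        an <- lg$grads[[nm]][i]
        expect_equal(an, fd, tolerance = 1e-4)
      }
    }
  })
})

test_that("node permutations preserving the pooling pairs leave logits unchanged", {
  model <- initGCNN(gcnnConfig(), seed = 7)
  withr::with_seed(16, x <- array(rnorm(2 * 1 * 8 * 5), c(2, 1, 8, 5)))
  # swapping within node pairs (1,2), (3,4), ... commutes with K8
  # convolution (uniform graph) and pairwise max-pooling
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7)
  xp <- x[, , perm, , drop = FALSE]
  expect_equal(unclass(gcnnForward(model, xp)),
               unclass(gcnnForward(model, x)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("training is deterministic and learns a separable toy problem", {
  graphs <- makeToyGraphs(nPerClass = 200, offset = 6, noise = 0.3, seed = 9)
  sp <- standardizeFeatures(splitDataset(graphs, seed = 4))
  # class margins >> noise: perfect validation accuracy within a few
  # passes at the published learning rate
  tcfg <- trainConfig(epochs = 15, seed = 11)
  tr1 <- trainModel(sp, gcnnConfig(), tcfg)
  expect_equal(max(tr1$history$val_accuracy), 1)
  expect_identical(nrow(tr1$history), 15L)
  tr2 <- trainModel(sp, gcnnConfig(), tcfg)
  expect_identical(tr1$model@weights, tr2$model@weights)
  expect_identical(tr1$history, tr2$history)
})

test_that("prediction is deterministic, batch-invariant and argmax-consistent", {
  graphs <- makeToyGraphs(nPerClass = 30, offset = 6, seed = 10)
  sp <- standardizeFeatures(splitDataset(graphs, seed = 6))
  tr <- trainModel(sp, gcnnConfig(), trainConfig(epochs = 3, seed = 8))
  pr <- predictStages(tr$model, sp@test)
  expect_identical(pr$labels, max.col(pr$probs) - 1L)
  # batch of one equals the same sample inside the batch
  single <- predictStages(tr$model, sp@test[3])
  expect_equal(single$probs[1, ], pr$probs[3, ], tolerance = 1e-12)
  # duplicated inputs give identical rows
  dup <- predictStages(tr$model, sp@test[c(1, 1)])
  expect_equal(dup$probs[1, ], dup$probs[2, ], tolerance = 1e-15)
  expect_error(predictStages(initGCNN(gcnnConfig()), sp@test),
               "not been trained")
})

test_that("weight archives round-trip through plain text", {
  graphs <- makeToyGraphs(nPerClass = 20, seed = 12)
  sp <- standardizeFeatures(splitDataset(graphs, seed = 2))
  tr <- trainModel(sp, gcnnConfig(), trainConfig(epochs = 1, seed = 3))
  p <- withr::local_tempfile()
  saveModelWeights(tr$model, p)
  m2 <- loadModelWeights(initGCNN(gcnnConfig()), p)
  expect_equal(m2@weights, tr$model@weights, tolerance = 1e-15)
  pr1 <- predictStages(tr$model, sp@test[1:5])
  pr2 <- predictStages(m2, sp@test[1:5])
  expect_equal(pr1$probs, pr2$probs, tolerance = 1e-12)
  # standardisation parameters travel with the archive: raw features
  # standardised through the loaded model match the split's own transform
  expect_equal(m2@config$featureMeans, sp@featureMeans, tolerance = 1e-12)
  raw <- makeToyGraphs(nPerClass = 20, seed = 12)
  std <- applyStandardization(raw, m2)
  ref <- sweep(sweep(raw[[1]]@nodeFeatures, 2, sp@featureMeans), 2,
               sp@featureSds, "/")
  expect_equal(std[[1]]@nodeFeatures, ref, tolerance = 1e-12)
})
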
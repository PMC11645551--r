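test_that("patch span rounds half-up and never drops below 1", {
  expect_identical(computePatchSpan(55, 8), 7L)
  expect_identical(computePatchSpan(100, 8), 13L)  # 12.5 rounds up
  expect_identical(computePatchSpan(8, 8), 1L)
  expect_identical(computePatchSpan(1, 8), 1L)
})

test_that("lattice adjacency has von Neumann degrees and matches the dense oracle", {
  # D = 2: every node has 2 lattice neighbours
  g2 <- buildAdjacency(2, normalize = "none")
  A2 <- as.matrix(g2@adjacency) - diag(4)
  expect_true(all(rowSums(A2) == 2))
  # D = 3: corner 2, edge 3, center 4 (pre-normalisation)
  A3 <- as.matrix(buildAdjacency(3, normalize = "none")@adjacency) - diag(9)
  deg <- rowSums(A3)
  expect_equal(deg[(2 - 1) * 3 + 2], 4)            # center (2,2) row-major
  expect_equal(sort(unique(deg)), c(2, 3, 4))
  expect_equal(sum(deg == 2), 4); expect_equal(sum(deg == 3), 4)
  # D = 5: normalised operator equals the dense brute-force build
  for (norm in c("sym", "row", "none")) {
    got <- as.matrix(buildAdjacency(5, normalize = norm)@adjacency)
    expect_equal(got, oracleAdjacencyDense(5, norm), tolerance = 1e-12)
  }
  # row mode is row-stochastic; sym is symmetric
  expect_equal(unname(Matrix::rowSums(buildAdjacency(4, "row")@adjacency)),
               rep(1, 16), tolerance = 1e-12)
  As <- buildAdjacency(4, "sym")@adjacency
  expect_equal(as.matrix(As), t(as.matrix(As)), tolerance = 1e-12)
  expect_error(buildAdjacency(0), ">= 1")
})

test_that("forward pass matches the dense chain oracle and stays positive", {
  D <- 3; C <- 4; K <- 2
  graph <- buildAdjacency(D)
  model <- newSuperResModel(C, c("a", "b"), hiddenDim = 6, seed = 1)
  # give the zero-initialised head non-trivial weights for the check
  model@W2 <- withSeed(2, matrix(rnorm(6 * K), 6, K))
  model@b <- c(0.3, -0.2)
  X <- withSeed(3, array(rnorm(D * D * C), c(D, D, C)))
  Z <- gcnForward(model, X, graph)
  Xflat <- matrix(aperm(X, c(2, 1, 3)), D * D, C)
  oracle <- oracleForwardDense(model@W0, model@W1, model@W2, model@b,
                               Xflat, oracleAdjacencyDense(D, "sym"))
  expect_equal(unname(Z), oracle, tolerance = 1e-6)
  expect_true(all(Z > 0))
  # zero weights and bias: eluPlusOne(0) = 1 everywhere
  z0 <- gcnForward(newSuperResModel(C, c("a", "b"), 6, seed = 0), X, graph)
  expect_equal(max(abs(z0 - 1)), 0, tolerance = 1e-12)
  expect_error(gcnForward(model, array(0, c(3, 3, 7)), graph), "channels")
})

test_that("weak-supervision loss is the filtered squared sum distance", {
  pred <- matrix(2, 4, 1)
  filt <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(weakSupervisionLoss(pred, filt, 10), (10 - 4)^2)
  # prediction summing exactly to the label gives zero
  expect_equal(weakSupervisionLoss(pred, filt, 4), 0)
  # one gene, label 10, in-disc sum 8 -> loss 4
  pred2 <- matrix(c(3, 5, 100, 100), 4, 1)
  # row-major node order: top row (nodes 1, 2) in the disc, sum = 8
  filt2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2, byrow = TRUE)
  expect_equal(weakSupervisionLoss(pred2, filt2, 10), 4)
  # random batch equals the per-spot loop oracle
  withSeed(4, {
    preds <- lapply(1:6, function(i) matrix(runif(9 * 3), 9, 3))
    filts <- lapply(1:6, function(i) matrix(runif(9) > 0.4, 3, 3))
    filts <- lapply(filts, function(f) { f[1, 1] <- TRUE; f })
    labels <- lapply(1:6, function(i) runif(3, 0, 5))
    expect_equal(weakSupervisionLoss(preds, filts, labels),
                 oracleLoss(preds, filts, labels), tolerance = 1e-9)
  })
})

test_that("spot patches center on the spot and carry the circular filter", {
  g <- SuperpixelGrid(20, 20, superpixelUm = 8, pixelSizeUm = 0.5)
  ch <- withSeed(5, array(rnorm(20 * 20 * 3), c(20, 20, 3)))
  fm <- new("MultimodalFeatureMap", channels = ch,
            channelRoles = c("hist", "pos_y", "pos_x"), grid = g)
  lay <- SpotLayout(rbind(c(76, 76), c(20, 140)), 55, 100)
  counts <- matrix(c(5, 7), 2, 1, dimnames = list(NULL, "g1"))
  se <- SpotExpression(counts, lay)
  patches <- buildSpotPatches(fm, se, D = 7)
  expect_length(patches, 2)
  # filter count equals brute-force count of centers within 27.5 um
  ctr <- c(76, 76)
  cnt <- 0
  for (m in 1:20) for (n in 1:20)
    if ((8 * n - 4 - ctr[1])^2 + (8 * m - 4 - ctr[2])^2 <= 27.5^2)
      cnt <- cnt + 1
  expect_equal(sum(patches[[1]]@filter), cnt)
  # features are the centered block (spot 1 center superpixel = (10, 10))
  expect_equal(patches[[1]]@features, ch[7:13, 7:13, ], ignore_attr = TRUE)
  expect_equal(patches[[1]]@label, c(g1 = 5))
  # spot 2 near the border: out-of-map nodes zero-padded, filter only in-map
  expect_true(all(patches[[2]]@features[, 1, ] == 0))
  expect_false(any(patches[[2]]@filter[, 1]))
  # D = 1: single-superpixel patch
  p1 <- buildSpotPatches(fm, SpotExpression(counts, SpotLayout(
    rbind(c(76, 76), c(20, 140)), diameterUm = 8, pitchUm = 100)), D = 1)
  expect_equal(dim(p1[[1]]@features), c(1L, 1L, 3L))
  expect_equal(p1[[1]]@features[1, 1, ], ch[10, 10, ])
  # spots at pitch >= D * superpixel span disjoint blocks
  blockOf <- function(center) {
    m0 <- floor(center[2] / 8) + 1; n0 <- floor(center[1] / 8) + 1
    expand.grid(r = (m0 - 3):(m0 + 3), c = (n0 - 3):(n0 + 3))
  }
  b1 <- blockOf(c(76, 76)); b2 <- blockOf(c(20, 140))
  expect_equal(nrow(merge(b1, b2)), 0)
  # off-map spot centers are skipped with a warning
  layOff <- SpotLayout(rbind(c(76, 76), c(500, 500)), 55, 100)
  expect_warning(pOff <- buildSpotPatches(fm, SpotExpression(counts, layOff),
                                          D = 7), "skipped")
  expect_length(pOff, 1)
})

test_that("training fits a constant-rate fixture and is seed-deterministic", {
  # constant features, labels = v * |filter|: exact solution is v everywhere
  D <- 5; C <- 3; v <- 2.5
  g <- SuperpixelGrid(30, 30, superpixelUm = 8, pixelSizeUm = 0.5)
  ch <- array(1, c(30, 30, C))
  fm <- new("MultimodalFeatureMap", channels = ch,
            channelRoles = c("hist", "pos_y", "pos_x"), grid = g)
  ctr <- as.matrix(expand.grid(x = c(60, 120, 180), y = c(60, 120, 180)))
  lay <- SpotLayout(ctr, diameterUm = 40, pitchUm = 60)
  graph <- buildAdjacency(D)
  patches0 <- buildSpotPatches(fm, SpotExpression(
    matrix(1, 9, 1, dimnames = list(NULL, "g1")), lay), D = D)
  labels <- vapply(patches0, function(p) v * sum(p@filter), numeric(1))
  se <- SpotExpression(matrix(labels, ncol = 1,
                              dimnames = list(NULL, "g1")), lay)
  patches <- buildSpotPatches(fm, se, D = D)
  fit <- trainSuperRes(patches, graph, trainConfig(epochs = 150, seed = 3),
                       hiddenDim = 16)
  expect_lt(tail(fit$lossHistory, 1), 1e-4 * fit$lossHistory[1] + 1e-6)
  pred <- gcnForward(fit$model, patches[[1]]@features, graph)
  expect_equal(mean(pred[as.vector(t(patches[[1]]@filter)), 1]), v,
               tolerance = 0.05)
  # determinism: identical seeds give identical histories and weights
  fit2 <- trainSuperRes(patches, graph, trainConfig(epochs = 150, seed = 3),
                        hiddenDim = 16)
  expect_identical(fit$lossHistory, fit2$lossHistory)
  expect_identical(fit$model@W2, fit2$model@W2)
  expect_error(trainSuperRes(patches[1], graph), "at least 2")
})

test_that("training treats identical gene columns identically", {
  sm <- smallBenchmark()
  bm <- sm$bm; fm <- sm$fm
  counts <- spotCounts(bm$spots)
  twin <- cbind(counts[, 1, drop = FALSE], counts[, 1, drop = FALSE])
  colnames(twin) <- c("copy1", "copy2")
  se <- SpotExpression(twin, bm$layout)
  graph <- buildAdjacency(7)
  patches <- buildSpotPatches(fm$featureMap, se, D = 7)
  fit <- trainSuperRes(patches, graph, trainConfig(epochs = 40, seed = 1),
                       hiddenDim = 32)
  pred <- gcnForward(fit$model, patches[[1]]@features, graph)
  expect_identical(unname(pred[, 1]), unname(pred[, 2]))
})

test_that("tiled inference equals independent per-tile prediction", {
  D <- 4; C <- 5; K <- 3
  graph <- buildAdjacency(D)
  model <- newSuperResModel(C, c("a", "b", "c"), hiddenDim = 8, seed = 2)
  model@W2 <- withSeed(6, matrix(rnorm(8 * K), 8, K))
  model@b <- withSeed(7, rnorm(K))
  g <- SuperpixelGrid(3 * D, 2 * D, superpixelUm = 8, pixelSizeUm = 0.5)
  ch <- withSeed(8, array(rnorm(12 * 8 * C), c(12, 8, C)))
  fm <- new("MultimodalFeatureMap", channels = ch,
            channelRoles = c(rep("hist", C - 2), "pos_y", "pos_x")[1:C],
            grid = g)
  mask <- matrix(TRUE, 12, 8)
  hr <- inferSuperRes(fm, model, graph, mask)
  vals <- expressionField(hr)
  for (i in 1:3) for (j in 1:2) {
    rows <- ((i - 1) * D + 1):(i * D); cols <- ((j - 1) * D + 1):(j * D)
    tileZ <- gcnForward(model, ch[rows, cols, , drop = FALSE], graph)
    blk <- aperm(array(tileZ, c(D, D, K)), c(2, 1, 3))
    expect_equal(vals[rows, cols, ], blk, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  # map of exactly one tile: output equals the reshaped forward pass
  g1 <- SuperpixelGrid(D, D, superpixelUm = 8, pixelSizeUm = 0.5)
  fm1 <- new("MultimodalFeatureMap",
             channels = ch[1:D, 1:D, , drop = FALSE],
             channelRoles = channelRoles(fm), grid = g1)
  hr1 <- inferSuperRes(fm1, model, graph, matrix(TRUE, D, D))
  z1 <- gcnForward(model, ch[1:D, 1:D, , drop = FALSE], graph)
  expect_equal(expressionField(hr1),
               aperm(array(z1, c(D, D, K)), c(2, 1, 3)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # all-false mask zeroes everything
  hr0 <- inferSuperRes(fm, model, graph, matrix(FALSE, 12, 8))
  expect_true(all(expressionField(hr0) == 0))
  expect_error(inferSuperRes(fm1, newSuperResModel(C + 1, "a", 8), graph,
                             matrix(TRUE, D, D)), "channels")
})

test_that("exported GCN features are the 512-dim layer-2 activations", {
  D <- 3; C <- 4
  graph <- buildAdjacency(D)
  model <- newSuperResModel(C, "a", hiddenDim = 512, seed = 5)
  g <- SuperpixelGrid(D, D, superpixelUm = 8, pixelSizeUm = 0.5)
  ch <- withSeed(9, array(rnorm(D * D * C), c(D, D, C)))
  fm <- new("MultimodalFeatureMap", channels = ch,
            channelRoles = c("hist", "hist", "pos_y", "pos_x"), grid = g)
  mask <- matrix(TRUE, D, D); mask[1, 1] <- FALSE
  feats <- exportGcnFeatures(fm, model, graph, mask)
  expect_identical(dim(feats), c(3L, 3L, 512L))
  expect_true(all(feats[1, 1, ] == 0))
  # equals the dense oracle's intermediate H2
  relu <- function(m) { m[m < 0] <- 0; m }
  Ad <- oracleAdjacencyDense(D, "sym")
  Xf <- matrix(aperm(ch, c(2, 1, 3)), D * D, C)
  H2 <- relu(Ad %*% relu(Ad %*% Xf %*% model@W0) %*% model@W1)
  blk <- aperm(array(H2, c(D, D, 512)), c(2, 1, 3))
  for (k in seq_len(512)) blk[, , k][!mask] <- 0
  expect_equal(feats, blk, tolerance = 1e-6)
})
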
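# Shared, memoised heavy runs so several test files can score the same
# trained model without retraining.

.benchCache <- new.env(parent = emptyenv())

# the default synthetic benchmark (96 x 96, 25 genes, seed 0)
defaultBenchmark <- function() {
  if (is.null(.benchCache$bm)) .benchCache$bm <- makeBenchmark(syntheticConfig())
  .benchCache$bm
}

# feature map + tissue mask for the default benchmark (fallback backbone)
defaultFeatures <- function() {
  if (is.null(.benchCache$fm)) {
    bm <- defaultBenchmark()
    .benchCache$fm <- buildFeatureMap(bm$image, 0.5, fallbackBackbone(0, 32))
  }
  .benchCache$fm
}

# full train (300 epochs) + infer on the default benchmark
defaultFit <- function() {
  if (is.null(.benchCache$fit)) {
    bm <- defaultBenchmark()
    fm <- defaultFeatures()
    D <- computePatchSpan(spotDiameter(bm$layout),
                          superpixelGridOf(bm$truth)@superpixelUm)
    graph <- buildAdjacency(D)
    patches <- buildSpotPatches(fm$featureMap, bm$spots, D)
    tr <- trainSuperRes(patches, graph, trainConfig(epochs = 300, seed = 0))
    grid <- superpixelGridOf(bm$truth)
    highres <- cropHighRes(inferSuperRes(fm$featureMap, tr$model, graph,
                                         fm$mask),
                           grid@nRows, grid@nCols)
    .benchCache$fit <- list(model = tr$model, graph = graph, D = D,
                            lossHistory = tr$lossHistory, highres = highres,
                            patches = patches)
  }
  .benchCache$fit
}

# a small fast benchmark for cheap end-to-end tests
smallBenchmark <- function() {
  if (is.null(.benchCache$small)) {
    cfg <- syntheticConfig(nRows = 32, nCols = 32, nGenes = 6, seed = 7)
    bm <- makeBenchmark(cfg)
    fm <- buildFeatureMap(bm$image, 0.5, fallbackBackbone(1, 8))
    .benchCache$small <- list(bm = bm, fm = fm)
  }
  .benchCache$small
}
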
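test_that("image preparation rescales and pads to tile multiples", {
  # already tile-aligned at target resolution: identity
  img <- withSeed(1, array(runif(224 * 224 * 3), c(224, 224, 3)))
  p <- prepareImage(img, 0.5)
  expect_identical(p@pixels, img)
  expect_identical(p@pad, c(0L, 0L, 0L, 0L))

  # one extra row pads to the next multiple
  img2 <- array(0.5, c(225, 224, 3))
  p2 <- prepareImage(img2, 0.5)
  expect_identical(dim(p2@pixels)[1:2], c(448L, 224L))
  expect_identical(p2@pad, c(0L, 223L, 0L, 0L))

  # rescaling doubles dims at 1.0 -> 0.5 um/px, then pads
  img3 <- array(0.5, c(300, 500, 3))
  p3 <- prepareImage(img3, 1.0)
  expect_identical(dim(p3@pixels)[1:2], c(672L, 1120L))
  expect_identical(p3@pad, c(0L, 72L, 0L, 120L))

  expect_error(prepareImage(array(0, c(10, 10, 2)), 0.5), "RGB")
})

test_that("tiling is a partition: reassembly reproduces the image", {
  img <- withSeed(2, array(runif(448 * 672 * 3), c(448, 672, 3)))
  p <- prepareImage(img, 0.5)
  tl <- tileImage(p)
  expect_equal(tl$nTileRows, 2L)
  expect_equal(tl$nTileCols, 3L)
  # tile (i, j) equals the corresponding pixel slice
  expect_identical(tl$tiles[[5]], img[225:448, 225:448, , drop = FALSE])
  rebuilt <- array(0, dim(img))
  for (i in 1:2) for (j in 1:3)
    rebuilt[((i - 1) * 224 + 1):(i * 224), ((j - 1) * 224 + 1):(j * 224), ] <-
      tl$tiles[[(i - 1) * 3 + j]]
  expect_identical(rebuilt, img)
})

test_that("fallback backbone is deterministic, local and discriminative", {
  bb <- fallbackBackbone(seed = 4, featureDim = 16)
  tile <- withSeed(3, array(runif(224 * 224 * 3), c(224, 224, 3)))
  f1 <- bb@apply(tile)
  expect_identical(dim(f1), c(14L, 14L, 16L))
  expect_identical(bb@apply(tile), f1)
  # same seed gives the same projection, different seed a different one
  expect_identical(fallbackBackbone(4, 16)@apply(tile), f1)
  expect_false(identical(fallbackBackbone(5, 16)@apply(tile), f1))
  # modifying one 16x16 patch changes only that patch's features
  tile2 <- tile
  tile2[33:48, 81:96, ] <- 0.123
  f2 <- bb@apply(tile2)
  changed <- apply(abs(f2 - f1), c(1, 2), sum) > 1e-12
  expect_identical(which(changed, arr.ind = TRUE),
                   matrix(c(3L, 6L), 1, dimnames = list(NULL, c("row", "col"))))
  # textured input activates nearly all channels
  varByChannel <- apply(f1, 3, function(m) var(as.vector(m)))
  expect_gte(mean(varByChannel > 1e-12), 0.9)
})

test_that("histology feature extraction assembles per-patch vectors seamlessly", {
  bb <- fallbackBackbone(0, 8)
  img <- withSeed(6, array(runif(224 * 448 * 3), c(224, 448, 3)))
  p <- prepareImage(img, 0.5)
  hist <- extractHistologyFeatures(p, bb)
  # one 224 tile = 14 x 14 = 196 patch positions
  expect_identical(dim(hist), c(14L, 28L, 8L))
  # constant image: spatially constant features
  pc <- prepareImage(array(0.7, c(224, 224, 3)), 0.5)
  hc <- extractHistologyFeatures(pc, bb)
  expect_lt(max(abs(sweep(hc, 3, hc[1, 1, ]))), 1e-12)
  # determinism across runs
  expect_identical(extractHistologyFeatures(p, bb), hist)
  # shape contract enforced
  bad <- new("HistologyBackbone", patchPx = 16L, tilePx = 224L,
             featureDim = 8L, apply = function(tile) array(0, c(7, 7, 8)),
             name = "bad")
  expect_error(extractHistologyFeatures(p, bad), "shape")
})

test_that("positional map encodes scaled 0-based row/col fractions", {
  pm <- positionalFeatureMap(4, 8, alpha = 1)
  expect_equal(pm[1, 1, ], c(0, 0))
  expect_equal(pm[3, 1, 1], 0.5)  # i = 2 (0-based) over nRows 4
  expect_equal(positionalFeatureMap(4, 8, alpha = 2), 2 * pm)
  # monotone in i and j
  expect_true(all(diff(pm[, 1, 1]) > 0))
  expect_true(all(diff(pm[1, , 2]) > 0))
})

test_that("RGB map is exact 16x16 block averaging in [0, 1]", {
  pc <- prepareImage(array(0.4, c(224, 224, 3)), 0.5)
  expect_equal(max(abs(rgbFeatureMap(pc) - 0.4)), 0, tolerance = 1e-12)
  # checkerboard of 0/1 pools to 0.5
  cb <- array(0, c(224, 224, 3))
  cb[] <- (outer(1:224, 1:224, "+") %% 2)
  expect_equal(unname(rgbFeatureMap(prepareImage(cb, 0.5))[1, 1, ]),
               rep(0.5, 3))
  img <- withSeed(8, array(runif(224 * 224 * 3), c(224, 224, 3)))
  p <- prepareImage(img, 0.5)
  expect_equal(rgbFeatureMap(p), oracleBlockMean(img), tolerance = 1e-12)
})

test_that("stacking orders channels hist/pos/rgb and is reversible", {
  g <- SuperpixelGrid(6, 6)
  hist <- withSeed(12, array(rnorm(6 * 6 * 8), c(6, 6, 8)))
  pos <- positionalFeatureMap(6, 6)
  rgb <- withSeed(13, array(runif(6 * 6 * 3), c(6, 6, 3)))
  fm <- stackFeatureMaps(hist, pos, rgb, g, standardize = FALSE)
  expect_identical(dim(featureChannels(fm))[3], 8L + 5L)
  expect_identical(channelRoles(fm),
                   c(rep("hist", 8), "pos_y", "pos_x",
                     "rgb_r", "rgb_g", "rgb_b"))
  ch <- featureChannels(fm)
  expect_identical(ch[, , 1:8], hist)
  expect_identical(ch[, , 9:10], pos)
  expect_identical(ch[, , 11:13], rgb)
  expect_error(stackFeatureMaps(hist, positionalFeatureMap(5, 6), rgb, g),
               "disagree")
  # standardisation: masked mean 0, sd 1 per histology channel
  fms <- stackFeatureMaps(hist, pos, rgb, g, standardize = TRUE)
  chs <- featureChannels(fms)
  expect_equal(mean(chs[, , 3]), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(chs[, , 3])), 1, tolerance = 1e-12)
})

test_that("tissue mask recovers a dark disc on a white slide", {
  # analytic disc: radius 60 superpixels on a 128 x 128 grid
  n <- 128
  img <- array(0.95, c(n * 16, n * 16, 3))
  ii <- matrix(seq_len(n * 16), n * 16, n * 16)
  jj <- t(ii)
  disc <- (ii - 1024)^2 + (jj - 1024)^2 <= (60 * 16)^2
  for (ch in 1:3) { pl <- img[, , ch]; pl[disc] <- 0.4; img[, , ch] <- pl }
  p <- prepareImage(img, 0.5)
  mask <- detectTissueMask(p)[1:n, 1:n]  # drop the tile-padding margin
  discSp <- (matrix(seq_len(n), n, n) - 64)^2 +
    (t(matrix(seq_len(n), n, n)) - 64)^2 <= 60^2
  jac <- sum(mask & discSp) / sum(mask | discSp)
  expect_gte(jac, 0.95)
  # uniform image: all-false + warning
  pu <- prepareImage(array(0.8, c(224, 224, 3)), 0.5)
  expect_warning(mu <- detectTissueMask(pu), "contrast|no tissue")
  expect_false(any(mu))
})

test_that("padded border superpixels are masked out", {
  img <- array(0.3, c(230, 224, 3))  # dark tissue, pads to 448 rows
  p <- prepareImage(img, 0.5)
  mask <- suppressWarnings(detectTissueMask(p))
  expect_false(any(mask[16:28, ]))  # rows beyond ceiling(230/16) are padding
})

test_that("feature-map cells align with image patches (locality property)", {
  bb <- fallbackBackbone(2, 8)
  img <- withSeed(14, array(runif(224 * 224 * 3), c(224, 224, 3)))
  p1 <- prepareImage(img, 0.5)
  img2 <- img
  img2[(7 * 16 + 1):(8 * 16), (2 * 16 + 1):(3 * 16), ] <- 0  # patch (8, 3)
  p2 <- prepareImage(img2, 0.5)
  h1 <- extractHistologyFeatures(p1, bb)
  h2 <- extractHistologyFeatures(p2, bb)
  diffmap <- apply(abs(h1 - h2), c(1, 2), sum) > 1e-12
  expect_identical(which(diffmap, arr.ind = TRUE),
                   matrix(c(8L, 3L), 1, dimnames = list(NULL, c("row", "col"))))
})
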
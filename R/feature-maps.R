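# Multimodal feature map construction from a histology image.
#
# The image is rescaled to a fixed physical pixel size (0.5 um/px) and
# padded so both dimensions divide into 224 x 224 tiles. A backbone maps
# each tile to per-16x16-patch feature vectors; each patch corresponds to
# one 8 x 8 um superpixel. Two positional channels and three pooled RGB
# channels are stacked on top of the histology channels.

#' Rescale and pad a histology image for tiling
#'
#' Bilinearly rescales the image so one pixel spans `targetPixelSizeUm`
#' micrometres, then zero-pads on the bottom and right up to the next
#' multiple of `tilePx`. Pad amounts are recorded so downstream outputs can
#' be cropped back to the tissue extent.
#'
#' @param image rows x cols x 3 numeric array; values in [0, 1] or 0-255
#'   (rescaled to [0, 1]).
#' @param sourcePixelSizeUm physical pixel size of `image`.
#' @param targetPixelSizeUm pixel size after rescaling (default 0.5).
#' @param tilePx tile size (default 224).
#' @return a [PreparedImage-class].
#' @export
prepareImage <- function(image, sourcePixelSizeUm,
                         targetPixelSizeUm = 0.5, tilePx = 224) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an RGB array (rows x cols x 3)")
  if (sourcePixelSizeUm <= 0) stop("sourcePixelSizeUm must be > 0")
  img <- image
  if (max(img) > 1 + 1e-9) img <- img / 255
  fac <- sourcePixelSizeUm / targetPixelSizeUm
  if (abs(fac - 1) > 1e-9) {
    newR <- round(dim(img)[1] * fac)
    newC <- round(dim(img)[2] * fac)
    # EBImage images are (x, y, channel) = (col, row, channel)
    eb <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
    eb <- EBImage::resize(eb, w = newC, h = newR, filter = "bilinear")
    img <- aperm(EBImage::imageData(eb), c(2, 1, 3))
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  padB <- (tilePx - dim(img)[1] %% tilePx) %% tilePx
  padR <- (tilePx - dim(img)[2] %% tilePx) %% tilePx
  if (padB > 0 || padR > 0) {
    out <- array(0, dim = c(dim(img)[1] + padB, dim(img)[2] + padR, 3))
    out[seq_len(dim(img)[1]), seq_len(dim(img)[2]), ] <- img
    img <- out
  }
  new("PreparedImage", pixels = img,
      pad = as.integer(c(0, padB, 0, padR)),
      sourcePixelSizeUm = sourcePixelSizeUm,
      pixelSizeUm = targetPixelSizeUm, tilePx = as.integer(tilePx))
}

#' Split a prepared image into tiles
#'
#' @param img a [PreparedImage-class].
#' @return list with `tiles` (list of tilePx x tilePx x 3 arrays in
#'   row-major tile order) and `nTileRows`, `nTileCols`.
#' @export
tileImage <- function(img) {
  px <- img@pixels; t <- img@tilePx
  nTR <- dim(px)[1] %/% t; nTC <- dim(px)[2] %/% t
  tiles <- vector("list", nTR * nTC)
  for (i in seq_len(nTR)) for (j in seq_len(nTC)) {
    tiles[[(i - 1) * nTC + j]] <-
      px[((i - 1) * t + 1):(i * t), ((j - 1) * t + 1):(j * t), , drop = FALSE]
  }
  list(tiles = tiles, nTileRows = nTR, nTileCols = nTC)
}

# per-patch summary statistics of one tile: mean, sd and mean |gradient|
# per channel, computed strictly within each patchPx x patchPx patch.
.patchStats <- function(tile, patchPx) {
  t <- dim(tile)[1]
  np <- t %/% patchPx
  m <- array(tile, dim = c(patchPx, np, patchPx, np, 3))
  mu <- apply(m, c(2, 4, 5), mean)
  sd_ <- sqrt(pmax(apply(m, c(2, 4, 5), function(v) mean(v^2)) - mu^2, 0))
  dx <- abs(m[, , 2:patchPx, , , drop = FALSE] -
            m[, , 1:(patchPx - 1), , , drop = FALSE])
  dy <- abs(m[2:patchPx, , , , , drop = FALSE] -
            m[1:(patchPx - 1), , , , , drop = FALSE])
  gx <- apply(dx, c(2, 4, 5), mean)
  gy <- apply(dy, c(2, 4, 5), mean)
  # (np, np, 12) descriptor
  out <- array(0, dim = c(np, np, 12))
  out[, , 1:3] <- mu; out[, , 4:6] <- sd_
  out[, , 7:9] <- gx; out[, , 10:12] <- gy
  out
}

#' Training-free deterministic histology backbone
#'
#' Satisfies the [HistologyBackbone-class] contract without any pretrained
#' weights: each 16 x 16 patch is summarised by 12 local statistics (per
#' RGB channel: mean, standard deviation, mean horizontal and vertical
#' absolute gradient) and expanded to `featureDim` channels by a fixed,
#' seed-determined random linear map. Features are strictly patch-local and
#' reproducible, so distinct tissue textures map to distinct features and
#' the same tile always maps to the same output.
#'
#' @param seed seed of the projection matrix.
#' @param featureDim number of output channels F (default 32).
#' @return a [HistologyBackbone-class].
#' @export
fallbackBackbone <- function(seed = 0, featureDim = 32) {
  proj <- withSeed(seed, {
    matrix(stats::rnorm(12 * featureDim), 12, featureDim) / sqrt(12)
  })
  f <- as.integer(featureDim)
  applyFn <- function(tile) {
    st <- .patchStats(tile, 16L)
    np <- dim(st)[1]
    flat <- matrix(st, np * np, 12) %*% proj
    array(flat, dim = c(np, np, f))
  }
  new("HistologyBackbone", patchPx = 16L, tilePx = 224L,
      featureDim = f, apply = applyFn,
      name = sprintf("fallback(seed=%d,F=%d)", as.integer(seed), f))
}

#' Extract the histology feature map
#'
#' Runs the backbone over every tile and assembles the per-patch feature
#' blocks into a seamless (rows/16) x (cols/16) x F map: one feature vector
#' per 16 x 16 pixel patch, i.e. per 8 x 8 um superpixel at 0.5 um/px.
#' A single 224 x 224 tile yields a 14 x 14 block of 196 patch vectors.
#'
#' @param img a [PreparedImage-class].
#' @param backbone a [HistologyBackbone-class].
#' @return numeric array (rows/16, cols/16, F).
#' @export
extractHistologyFeatures <- function(img, backbone) {
  tl <- tileImage(img)
  patchesPerTile <- backbone@tilePx %/% backbone@patchPx
  F <- backbone@featureDim
  nR <- tl$nTileRows * patchesPerTile
  nC <- tl$nTileCols * patchesPerTile
  out <- array(0, dim = c(nR, nC, F))
  for (i in seq_len(tl$nTileRows)) for (j in seq_len(tl$nTileCols)) {
    blk <- backbone@apply(tl$tiles[[(i - 1) * tl$nTileCols + j]])
    if (!identical(dim(blk), as.integer(c(patchesPerTile, patchesPerTile, F))))
      stop(sprintf("backbone output shape (%s) != expected (%d, %d, %d)",
                   paste(dim(blk), collapse = ", "),
                   patchesPerTile, patchesPerTile, F))
    out[((i - 1) * patchesPerTile + 1):(i * patchesPerTile),
        ((j - 1) * patchesPerTile + 1):(j * patchesPerTile), ] <- blk
  }
  out
}

#' Positional feature map
#'
#' Two channels encoding normalised grid position: channel 1 (pos_y) is
#' `alpha * i / nRows` and channel 2 (pos_x) is `alpha * j / nCols` with
#' 0-based indices, so values lie in [0, alpha).
#'
#' @param nRows,nCols grid dimensions.
#' @param alpha positional scale (default 1).
#' @return numeric array (nRows, nCols, 2).
#' @export
positionalFeatureMap <- function(nRows, nCols, alpha = 1) {
  out <- array(0, dim = c(nRows, nCols, 2))
  out[, , 1] <- matrix(alpha * (seq_len(nRows) - 1) / nRows, nRows, nCols)
  out[, , 2] <- matrix(alpha * (seq_len(nCols) - 1) / nCols, nRows, nCols,
                       byrow = TRUE)
  out
}

#' RGB feature map by average pooling
#'
#' Downsamples the prepared image to superpixel resolution by
#' non-overlapping 16 x 16 average pooling per channel; values remain in
#' [0, 1].
#'
#' @param img a [PreparedImage-class].
#' @param patchPx pooling window (default 16).
#' @return numeric array (rows/16, cols/16, 3).
#' @export
rgbFeatureMap <- function(img, patchPx = 16L) {
  px <- img@pixels
  nR <- dim(px)[1] %/% patchPx; nC <- dim(px)[2] %/% patchPx
  m <- array(px, dim = c(patchPx, nR, patchPx, nC, 3))
  apply(m, c(2, 4, 5), mean)
}

#' Stack histology, positional and RGB maps into one multimodal map
#'
#' Channel order is [histology..., pos_y, pos_x, rgb_r, rgb_g, rgb_b], so
#' C = F + 5. Histology channels are standardised (zero mean, unit
#' variance over in-mask superpixels) by default so the large histology
#' block does not drown the 5 positional/RGB channels.
#'
#' @param hist F-channel histology array (rows, cols, F).
#' @param pos 2-channel positional array.
#' @param rgb 3-channel pooled RGB array.
#' @param grid the [SuperpixelGrid-class] of the maps.
#' @param standardize standardise histology channels (default TRUE).
#' @param mask optional logical mask defining the standardisation support.
#' @return a [MultimodalFeatureMap-class].
#' @export
stackFeatureMaps <- function(hist, pos, rgb, grid, standardize = TRUE,
                             mask = NULL) {
  d <- dim(hist)[1:2]
  if (!identical(d, dim(pos)[1:2]) || !identical(d, dim(rgb)[1:2]))
    stop("feature maps disagree in spatial dims: hist ",
         paste(dim(hist)[1:2], collapse = "x"), ", pos ",
         paste(dim(pos)[1:2], collapse = "x"), ", rgb ",
         paste(dim(rgb)[1:2], collapse = "x"))
  F <- dim(hist)[3]
  if (standardize) {
    sel <- if (is.null(mask)) rep(TRUE, prod(d)) else as.vector(mask)
    for (k in seq_len(F)) {
      ch <- hist[, , k]
      mu <- mean(ch[sel]); sd_ <- stats::sd(ch[sel])
      hist[, , k] <- if (is.na(sd_) || sd_ < 1e-12) ch - mu else (ch - mu) / sd_
    }
  }
  channels <- array(0, dim = c(d[1], d[2], F + 5L))
  channels[, , seq_len(F)] <- hist
  channels[, , F + 1:2] <- pos
  channels[, , F + 3:5] <- rgb
  new("MultimodalFeatureMap", channels = channels,
      channelRoles = c(rep("hist", F), "pos_y", "pos_x",
                       "rgb_r", "rgb_g", "rgb_b"),
      grid = grid)
}

#' Detect the tissue mask at superpixel resolution
#'
#' Pools the image to grayscale superpixel resolution, thresholds with
#' Otsu's method (tissue = the darker side, the H&E convention of stained
#' tissue on a bright background), applies 3 x 3 morphological closing and
#' drops connected components smaller than 0.1% of the grid area. Padded
#' border superpixels are background by construction and are excluded from
#' the threshold estimate and the mask.
#'
#' @param img a [PreparedImage-class].
#' @param patchPx pooling window (default 16).
#' @return logical matrix (rows/16, cols/16); TRUE = tissue. All-FALSE with
#'   a warning when no tissue is detectable.
#' @export
detectTissueMask <- function(img, patchPx = 16L) {
  rgb <- rgbFeatureMap(img, patchPx)
  g <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  nR <- nrow(g); nC <- ncol(g)
  validR <- seq_len(nR - ceiling(img@pad[2] / patchPx))
  validC <- seq_len(nC - ceiling(img@pad[4] / patchPx))
  gv <- g[validR, validC]
  if (stats::sd(gv) < 1e-8) {
    warning("image has no contrast; returning an all-background mask")
    return(matrix(FALSE, nR, nC))
  }
  thr <- EBImage::otsu(EBImage::Image(t(gv)), range = c(0, 1))
  mask <- matrix(FALSE, nR, nC)
  mask[validR, validC] <- gv < thr
  if (!any(mask)) {
    warning("no tissue detected; returning an all-background mask")
    return(mask)
  }
  eb <- EBImage::Image(t(mask) * 1)
  eb <- EBImage::closing(eb, EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(eb)
  labm <- t(EBImage::imageData(lab))
  sizes <- table(labm[labm > 0])
  keep <- as.integer(names(sizes)[sizes >= 0.001 * nR * nC])
  out <- matrix(labm %in% keep, nR, nC)
  out[-validR, ] <- FALSE
  if (length(validC) < nC) out[, -validC] <- FALSE
  out
}

#' Build the full multimodal feature map from an image
#'
#' Convenience pipeline: prepare the image, detect the tissue mask, extract
#' histology features with the given backbone, compute positional and RGB
#' maps and stack everything.
#'
#' @param image RGB array or a [PreparedImage-class].
#' @param sourcePixelSizeUm pixel size of `image` (ignored when already
#'   prepared).
#' @param backbone a [HistologyBackbone-class]
#'   (default [fallbackBackbone()]).
#' @param alpha positional scale (default 1).
#' @param standardize standardise histology channels (default TRUE).
#' @return list with `featureMap` ([MultimodalFeatureMap-class]), `mask`
#'   (logical matrix) and `prepared` ([PreparedImage-class]).
#' @export
buildFeatureMap <- function(image, sourcePixelSizeUm = 0.5,
                            backbone = fallbackBackbone(),
                            alpha = 1, standardize = TRUE) {
  img <- if (is(image, "PreparedImage")) image
         else prepareImage(image, sourcePixelSizeUm,
                           tilePx = backbone@tilePx)
  mask <- detectTissueMask(img, backbone@patchPx)
  hist <- extractHistologyFeatures(img, backbone)
  pos <- positionalFeatureMap(nrow(mask), ncol(mask), alpha)
  rgb <- rgbFeatureMap(img, backbone@patchPx)
  grid <- SuperpixelGrid(nrow(mask), ncol(mask),
                         superpixelUm = backbone@patchPx * img@pixelSizeUm,
                         pixelSizeUm = img@pixelSizeUm)
  fm <- stackFeatureMaps(hist, pos, rgb, grid, standardize = standardize,
                         mask = mask)
  list(featureMap = fm, mask = mask, prepared = img)
}
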
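#' @import methods
#' @importFrom Matrix sparseMatrix bdiag Diagonal rowSums colSums t crossprod
NULL

#' SuperpixelGrid: geometry of the super-resolution output grid
#'
#' Describes a regular grid of square superpixels laid over the tissue in
#' physical coordinates. Each superpixel is `superpixelUm` micrometres on a
#' side (8 um by default, roughly one cell) and corresponds to a
#' `superpixelUm / pixelSizeUm` pixel square of the rescaled histology image
#' (16 x 16 px at the default 0.5 um/px). Coordinates are physical
#' micrometres with the origin at the top-left of the rescaled image, x
#' rightward and y downward; grid cell (m, n) = (row, col) covers the
#' half-open square [ (n-1)*s, n*s ) x [ (m-1)*s, m*s ) shifted by
#' `originUm`.
#'
#' @slot originUm numeric(2), physical (x, y) offset of the grid origin.
#' @slot superpixelUm side length of one superpixel in micrometres.
#' @slot nRows,nCols grid dimensions.
#' @slot pixelSizeUm physical size of one image pixel after rescaling.
#' @export
setClass("SuperpixelGrid",
  representation(originUm = "numeric", superpixelUm = "numeric",
                 nRows = "integer", nCols = "integer",
                 pixelSizeUm = "numeric"),
  prototype(originUm = c(0, 0), superpixelUm = 8, nRows = 1L, nCols = 1L,
            pixelSizeUm = 0.5))

setValidity("SuperpixelGrid", function(object) {
  msg <- character()
  if (length(object@originUm) != 2L)
    msg <- c(msg, "originUm must have length 2")
  if (object@superpixelUm <= 0)
    msg <- c(msg, "superpixelUm must be > 0")
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  span <- object@superpixelUm / object@pixelSizeUm
  if (object@pixelSizeUm <= 0 || abs(span - round(span)) > 1e-8 || span < 1)
    msg <- c(msg, "superpixelUm / pixelSizeUm must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' SpotLayout: centers and geometry of circular capture spots
#'
#' Visium-style spot geometry: circular capture areas of diameter
#' `diameterUm` (55 um by default) whose centers sit on a hexagonal or
#' square lattice with center-to-center distance `pitchUm` (100 um by
#' default), or at explicitly supplied positions.
#'
#' @slot centersUm numeric matrix (spots x 2), columns x and y in um.
#' @slot diameterUm spot diameter in micrometres.
#' @slot pitchUm center-to-center distance in micrometres.
#' @slot lattice one of "hex", "square", "explicit".
#' @export
setClass("SpotLayout",
  representation(centersUm = "matrix", diameterUm = "numeric",
                 pitchUm = "numeric", lattice = "character"))

setValidity("SpotLayout", function(object) {
  msg <- character()
  cc <- object@centersUm
  if (!is.numeric(cc) || ncol(cc) != 2L)
    msg <- c(msg, "centersUm must be a numeric matrix with 2 columns")
  if (object@diameterUm <= 0) msg <- c(msg, "diameterUm must be > 0")
  if (object@diameterUm > object@pitchUm + 1e-9)
    msg <- c(msg, "diameterUm must not exceed pitchUm")
  if (nrow(cc) > 1L && anyDuplicated(cc) > 0L)
    msg <- c(msg, "spot centers must be pairwise distinct")
  if (!object@lattice %in% c("hex", "square", "explicit"))
    msg <- c(msg, "lattice must be hex, square or explicit")
  if (length(msg)) msg else TRUE
})

#' SpotExpression: observed (or simulated) spot-level expression
#'
#' A spots x genes non-negative count matrix together with the spot
#' geometry. Row i of `counts` is the expression captured by the spot whose
#' center is row i of the layout.
#'
#' @slot counts numeric matrix, spots x genes, column names = gene names.
#' @slot layout a [SpotLayout-class].
#' @export
setClass("SpotExpression",
  representation(counts = "matrix", layout = "SpotLayout"))

setValidity("SpotExpression", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  gn <- colnames(object@counts)
  if (is.null(gn) || anyDuplicated(gn))
    msg <- c(msg, "counts must have unique gene (column) names")
  if (nrow(object@counts) != nrow(object@layout@centersUm))
    msg <- c(msg, sprintf("counts has %d rows but layout has %d centers",
                          nrow(object@counts), nrow(object@layout@centersUm)))
  if (length(msg)) msg else TRUE
})

#' CellTable: per-cell expression with spatial geometry
#'
#' Xenium-style single-cell input: one expression vector per cell plus its
#' centroid and area. Footprints are axis-aligned boxes (xmin, ymin, xmax,
#' ymax); when absent, a square of the stated area centered on the centroid
#' is used for area-weighted binning.
#'
#' @slot expression numeric matrix, cells x genes, column names = gene names.
#' @slot centroidsUm numeric matrix, cells x 2 (x, y) in um.
#' @slot areasUm2 numeric vector of per-cell areas, all > 0.
#' @slot footprints numeric matrix cells x 4 (xmin, ymin, xmax, ymax) or a
#'   0-row matrix when only centroid + area are known.
#' @export
setClass("CellTable",
  representation(expression = "matrix", centroidsUm = "matrix",
                 areasUm2 = "numeric", footprints = "matrix"),
  prototype(footprints = matrix(numeric(), 0, 4)))

setValidity("CellTable", function(object) {
  msg <- character()
  n <- nrow(object@expression)
  if (any(object@expression < 0)) msg <- c(msg, "expression must be non-negative")
  if (nrow(object@centroidsUm) != n || ncol(object@centroidsUm) != 2L)
    msg <- c(msg, "centroidsUm must be cells x 2")
  if (length(object@areasUm2) != n) msg <- c(msg, "areasUm2 length mismatch")
  if (any(object@areasUm2 <= 0)) msg <- c(msg, "areasUm2 must be > 0")
  fp <- object@footprints
  if (nrow(fp) > 0L) {
    if (nrow(fp) != n || ncol(fp) != 4L)
      msg <- c(msg, "footprints must be cells x 4 (xmin, ymin, xmax, ymax)")
    else {
      a <- (fp[, 3] - fp[, 1]) * (fp[, 4] - fp[, 2])
      bad <- abs(a - object@areasUm2) > 1e-6 * pmax(object@areasUm2, 1e-12)
      if (any(bad))
        msg <- c(msg, "footprint areas disagree with areasUm2 beyond 1e-6 relative")
    }
  }
  if (length(msg)) msg else TRUE
})

#' HighResExpression: a superpixel-resolution expression field
#'
#' The central output (and simulation ground-truth) container: a rows x
#' cols x genes non-negative array over a [SuperpixelGrid-class], with a
#' logical tissue mask. Values outside the mask are exactly zero.
#'
#' @slot values numeric array (nRows, nCols, genes); dimnames[[3]] = genes.
#' @slot mask logical matrix (nRows, nCols), TRUE = tissue.
#' @slot grid a [SuperpixelGrid-class].
#' @export
setClass("HighResExpression",
  representation(values = "array", mask = "matrix", grid = "SuperpixelGrid"))

setValidity("HighResExpression", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3-D array")
  else {
    if (d[1] != object@grid@nRows || d[2] != object@grid@nCols)
      msg <- c(msg, "values dims disagree with grid")
    if (!identical(dim(object@mask), d[1:2]))
      msg <- c(msg, "mask dims disagree with values")
    gn <- dimnames(object@values)[[3]]
    if (is.null(gn) || anyDuplicated(gn))
      msg <- c(msg, "values must carry unique gene names in dimnames[[3]]")
    if (any(object@values < 0)) msg <- c(msg, "values must be non-negative")
    out <- !object@mask
    if (any(out) && any(object@values[rep(out, d[3])] != 0))
      msg <- c(msg, "values outside the mask must be exactly 0")
  }
  if (length(msg)) msg else TRUE
})

#' PreparedImage: a rescaled, tile-aligned histology image
#'
#' RGB image rescaled to `pixelSizeUm` micrometres per pixel and zero-padded
#' (bottom/right) so both dimensions are multiples of the tile size. Values
#' are doubles in [0, 1]; the pad record allows outputs to be cropped back.
#'
#' @slot pixels numeric array (rows, cols, 3), values in [0, 1].
#' @slot pad integer(4): pixels added (top, bottom, left, right).
#' @slot sourcePixelSizeUm pixel size of the original image.
#' @slot pixelSizeUm pixel size after rescaling.
#' @slot tilePx tile size both dimensions are divisible by.
#' @export
setClass("PreparedImage",
  representation(pixels = "array", pad = "integer",
                 sourcePixelSizeUm = "numeric", pixelSizeUm = "numeric",
                 tilePx = "integer"))

setValidity("PreparedImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "pixels must be rows x cols x 3")
  else if (d[1] %% object@tilePx != 0L || d[2] %% object@tilePx != 0L)
    msg <- c(msg, sprintf("image dims (%d x %d) not divisible by tile size %d",
                          d[1], d[2], object@tilePx))
  if (length(object@pad) != 4L) msg <- c(msg, "pad must be integer(4)")
  if (length(msg)) msg else TRUE
})

#' HistologyBackbone: the tile-to-features extractor contract
#'
#' Any feature extractor mapping a `tilePx` x `tilePx` x 3 RGB tile to a
#' (tilePx/patchPx) x (tilePx/patchPx) x featureDim block of per-patch
#' feature vectors, deterministically. Pretrained pathology vision
#' transformers satisfy this contract; [fallbackBackbone()] provides a
#' training-free deterministic extractor so the package runs without any
#' model download.
#'
#' @slot patchPx patch size in pixels (16: one patch = one superpixel).
#' @slot tilePx tile size in pixels (224).
#' @slot featureDim number of feature channels F.
#' @slot apply function(tile array tilePx x tilePx x 3) -> array 14 x 14 x F.
#' @slot name human-readable identifier.
#' @export
setClass("HistologyBackbone",
  representation(patchPx = "integer", tilePx = "integer",
                 featureDim = "integer", apply = "function",
                 name = "character"),
  prototype(patchPx = 16L, tilePx = 224L))

setValidity("HistologyBackbone", function(object) {
  msg <- character()
  if (object@tilePx %% object@patchPx != 0L)
    msg <- c(msg, "tilePx must be a multiple of patchPx")
  if (object@featureDim < 1L) msg <- c(msg, "featureDim must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MultimodalFeatureMap: stacked per-superpixel descriptors
#'
#' The channel-stacked field feeding the graph network: F histology
#' channels, 2 positional channels (row and column fractions scaled by
#' alpha) and 3 pooled RGB channels, i.e. C = F + 5 channels per
#' superpixel.
#'
#' @slot channels numeric array (nRows, nCols, C).
#' @slot channelRoles character(C) in {hist, pos_y, pos_x, rgb_r, rgb_g, rgb_b}.
#' @slot grid a [SuperpixelGrid-class].
#' @export
setClass("MultimodalFeatureMap",
  representation(channels = "array", channelRoles = "character",
                 grid = "SuperpixelGrid"))

setValidity("MultimodalFeatureMap", function(object) {
  msg <- character()
  d <- dim(object@channels)
  if (length(d) != 3L) msg <- c(msg, "channels must be a 3-D array")
  else {
    if (length(object@channelRoles) != d[3])
      msg <- c(msg, "channelRoles length must equal the channel count")
    if (d[1] != object@grid@nRows || d[2] != object@grid@nCols)
      msg <- c(msg, "channels dims disagree with grid")
    ok <- object@channelRoles %in% c("hist", "pos_y", "pos_x",
                                     "rgb_r", "rgb_g", "rgb_b")
    if (!all(ok)) msg <- c(msg, "unknown channel role")
  }
  if (length(msg)) msg else TRUE
})

#' SpotPatch: one spot's D x D feature block and weak label
#'
#' Training unit for weak supervision: the D x D x C block of the
#' multimodal map centered on a spot, the circular filter selecting
#' superpixels whose centers fall inside the spot radius, and the observed
#' spot expression vector acting as the label for the in-disc sum.
#'
#' @slot features numeric array (D, D, C); out-of-map entries zero-padded.
#' @slot filter logical matrix (D, D); TRUE = superpixel center inside the
#'   spot disc (and inside the map).
#' @slot label numeric(K) observed spot expression.
#' @slot spotId integer index into the layout.
#' @export
setClass("SpotPatch",
  representation(features = "array", filter = "matrix", label = "numeric",
                 spotId = "integer"))

setValidity("SpotPatch", function(object) {
  msg <- character()
  d <- dim(object@features)
  if (length(d) != 3L || d[1] != d[2]) msg <- c(msg, "features must be D x D x C")
  else if (!identical(dim(object@filter), d[1:2]))
    msg <- c(msg, "filter dims disagree with features")
  if (sum(object@filter) < 1L) msg <- c(msg, "filter must select >= 1 superpixel")
  if (length(msg)) msg else TRUE
})

#' GridGraph: the shared D x D lattice graph
#'
#' Nodes are the D^2 superpixels of a patch in row-major order; each node is
#' connected to its four closest neighbours by physical distance (the
#' von Neumann neighbourhood on the square lattice). Self-loops are added
#' and the adjacency normalised (symmetric by default) before convolution.
#'
#' @slot adjacency sparse symmetric D^2 x D^2 matrix (normalised, with
#'   self-loops unless built with normalize = "none").
#' @slot D patch side length in superpixels.
#' @slot normalization one of "sym", "row", "none".
#' @export
setClass("GridGraph",
  representation(adjacency = "Matrix", D = "integer",
                 normalization = "character"))

#' SuperResModel: the two-layer GCN with non-negative output head
#'
#' Weights of the network mapping a D^2 x C node-feature matrix to a
#' D^2 x K non-negative expression matrix: two graph convolutions with ReLU
#' (C -> hidden -> hidden, hidden = 512) followed by a linear head with
#' elu(x) + 1 output activation.
#'
#' @slot W0 C x hidden; @slot W1 hidden x hidden; @slot W2 hidden x K.
#' @slot b numeric(K) output bias.
#' @slot hiddenDim hidden width (512).
#' @slot geneNames character(K).
#' @slot seed RNG seed the weights were initialised from.
#' @export
setClass("SuperResModel",
  representation(W0 = "matrix", W1 = "matrix", W2 = "matrix", b = "numeric",
                 hiddenDim = "integer", geneNames = "character",
                 seed = "integer"))

setValidity("SuperResModel", function(object) {
  msg <- character()
  h <- object@hiddenDim
  if (ncol(object@W0) != h || !identical(dim(object@W1), c(h, h)) ||
      nrow(object@W2) != h)
    msg <- c(msg, "weight shapes disagree with hiddenDim")
  if (length(object@b) != ncol(object@W2))
    msg <- c(msg, "bias length must equal the gene count")
  if (length(object@geneNames) != ncol(object@W2))
    msg <- c(msg, "geneNames length must equal the gene count")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: optimisation settings for weak supervision
#'
#' @slot learningRate Adam step size.
#' @slot batchSize spots per gradient step.
#' @slot epochs maximum epochs.
#' @slot seed RNG seed controlling init and batch shuffling.
#' @slot patience epochs without improvement before early stop.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer", patience = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0 || object@batchSize < 1L ||
      object@epochs < 1L || object@patience < 1L)
    "learningRate, batchSize, epochs and patience must be positive"
  else TRUE
})

#' GeneMetrics: per-gene evaluation table with summaries
#'
#' @slot perGene data.frame with columns gene, rmse, ssim, pcc, mae and a
#'   logical `constant` flag for zero-variance genes (excluded from
#'   summaries).
#' @slot summary data.frame with rows median and mean over non-flagged genes.
#' @export
setClass("GeneMetrics",
  representation(perGene = "data.frame", summary = "data.frame"))

#' SyntheticConfig: settings of the synthetic benchmark generator
#'
#' @slot nRows,nCols superpixel grid dimensions.
#' @slot nGenes number of genes.
#' @slot nFactors number of latent spatial factors.
#' @slot patterns pattern families cycled over factors.
#' @slot noiseModel "poisson" or "gaussian".
#' @slot noiseScale relative sd of gaussian noise (ignored for poisson).
#' @slot textureAmplitude pixel-level noise added to the rendered image.
#' @slot depthRange range of per-gene peak mean counts per superpixel.
#' @slot seed master seed; fixes every random draw.
#' @export
setClass("SyntheticConfig",
  representation(nRows = "integer", nCols = "integer", nGenes = "integer",
                 nFactors = "integer", patterns = "character",
                 noiseModel = "character", noiseScale = "numeric",
                 textureAmplitude = "numeric", depthRange = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nRows < 8L || object@nCols < 8L)
    msg <- c(msg, "grid must be at least 8 x 8 superpixels")
  if (object@nGenes < 1L || object@nFactors < 1L)
    msg <- c(msg, "nGenes and nFactors must be >= 1")
  if (!object@noiseModel %in% c("poisson", "gaussian"))
    msg <- c(msg, "noiseModel must be poisson or gaussian")
  if (length(object@depthRange) != 2L || any(object@depthRange <= 0))
    msg <- c(msg, "depthRange must be two positive numbers")
  if (length(msg)) msg else TRUE
})
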
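# Constructors and grid geometry.

#' Create a superpixel grid
#'
#' @param nRows,nCols grid dimensions in superpixels.
#' @param superpixelUm superpixel side length in micrometres (default 8,
#'   roughly one cell).
#' @param pixelSizeUm physical size of one rescaled image pixel (default
#'   0.5 um, so one superpixel spans 16 x 16 pixels).
#' @param originUm physical (x, y) offset of the grid origin.
#' @return a [SuperpixelGrid-class].
#' @export
SuperpixelGrid <- function(nRows, nCols, superpixelUm = 8,
                           pixelSizeUm = 0.5, originUm = c(0, 0)) {
  new("SuperpixelGrid", nRows = as.integer(nRows), nCols = as.integer(nCols),
      superpixelUm = superpixelUm, pixelSizeUm = pixelSizeUm,
      originUm = as.numeric(originUm))
}

#' Physical centers of every superpixel
#'
#' @param grid a [SuperpixelGrid-class].
#' @return list with `x` (length nCols) and `y` (length nRows): center
#'   coordinates in micrometres of grid columns and rows.
#' @export
superpixelCenters <- function(grid) {
  s <- grid@superpixelUm
  list(x = grid@originUm[1] + (seq_len(grid@nCols) - 0.5) * s,
       y = grid@originUm[2] + (seq_len(grid@nRows) - 0.5) * s)
}

#' Create a spot layout from explicit centers
#'
#' @param centersUm spots x 2 matrix of (x, y) centers in micrometres.
#' @param diameterUm spot diameter (default 55 um).
#' @param pitchUm center-to-center distance (default 100 um).
#' @param lattice lattice tag; "explicit" for arbitrary centers.
#' @return a [SpotLayout-class].
#' @export
SpotLayout <- function(centersUm, diameterUm = 55, pitchUm = 100,
                       lattice = "explicit") {
  centersUm <- as.matrix(centersUm)
  colnames(centersUm) <- c("x", "y")
  new("SpotLayout", centersUm = centersUm, diameterUm = diameterUm,
      pitchUm = pitchUm, lattice = lattice)
}

#' Tile a bounding box with evenly spaced pseudo-spots
#'
#' Generates Visium-like spot centers covering a rectangular region. Spots
#' keep a full radius of clearance from the box edge and the lattice is
#' centered inside the box. The hexagonal lattice (the Visium arrangement)
#' spaces rows by `pitch * sqrt(3)/2` and offsets alternate rows by
#' `pitch / 2`; the square lattice uses the pitch on both axes.
#'
#' @param bboxUm numeric(4): xmin, ymin, xmax, ymax in micrometres.
#' @param diameterUm spot diameter (default 55).
#' @param pitchUm center-to-center distance (default 100).
#' @param lattice "hex" (default) or "square".
#' @return a [SpotLayout-class].
#' @export
makeSpotLayout <- function(bboxUm, diameterUm = 55, pitchUm = 100,
                           lattice = c("hex", "square")) {
  lattice <- match.arg(lattice)
  stopifnot(length(bboxUm) == 4, diameterUm > 0, pitchUm >= diameterUm)
  r <- diameterUm / 2
  xmin <- bboxUm[1] + r; xmax <- bboxUm[3] - r
  ymin <- bboxUm[2] + r; ymax <- bboxUm[4] - r
  if (xmax < xmin - 1e-9 || ymax < ymin - 1e-9)
    stop("bbox too small: no spot fits with diameter ", diameterUm)
  centerLattice <- function(lo, hi, step) {
    n <- floor((hi - lo) / step + 1e-9) + 1
    lo + (hi - lo - (n - 1) * step) / 2 + (seq_len(n) - 1) * step
  }
  if (lattice == "square") {
    xs <- centerLattice(xmin, xmax, pitchUm)
    ys <- centerLattice(ymin, ymax, pitchUm)
    centers <- cbind(x = rep(xs, times = length(ys)),
                     y = rep(ys, each = length(xs)))
  } else {
    dy <- pitchUm * sqrt(3) / 2
    ys <- centerLattice(ymin, ymax, dy)
    xs0 <- centerLattice(xmin, xmax, pitchUm)
    rows <- lapply(seq_along(ys), function(i) {
      off <- if (i %% 2 == 0) pitchUm / 2 else 0
      x <- xs0 + off
      x <- x[x >= xmin - 1e-9 & x <= xmax + 1e-9]
      if (length(x)) cbind(x = x, y = ys[i]) else NULL
    })
    centers <- do.call(rbind, rows)
  }
  if (is.null(centers) || nrow(centers) == 0)
    stop("bbox too small: no spot fits")
  SpotLayout(centers, diameterUm, pitchUm, lattice)
}

#' Attach counts to a layout
#'
#' @param counts spots x genes non-negative matrix; column names = genes.
#' @param layout a [SpotLayout-class] with one center per counts row.
#' @return a [SpotExpression-class].
#' @export
SpotExpression <- function(counts, layout) {
  counts <- as.matrix(counts)
  new("SpotExpression", counts = counts, layout = layout)
}

#' Build a cell table
#'
#' @param expression cells x genes non-negative matrix (colnames = genes).
#' @param centroidsUm cells x 2 (x, y) centroids in micrometres.
#' @param areasUm2 per-cell areas; must be > 0.
#' @param footprints optional cells x 4 (xmin, ymin, xmax, ymax) boxes;
#'   default: squares of the stated area centered on the centroids.
#' @return a [CellTable-class].
#' @export
CellTable <- function(expression, centroidsUm, areasUm2, footprints = NULL) {
  if (any(areasUm2 <= 0)) stop("zero-area cell: all areasUm2 must be > 0")
  if (is.null(footprints)) footprints <- matrix(numeric(), 0, 4)
  new("CellTable", expression = as.matrix(expression),
      centroidsUm = as.matrix(centroidsUm), areasUm2 = as.numeric(areasUm2),
      footprints = as.matrix(footprints))
}

#' Wrap a field array as HighResExpression
#'
#' @param values rows x cols x genes non-negative array; dimnames[[3]] =
#'   gene names (supplied via `geneNames` if absent).
#' @param mask logical tissue mask; values outside are forced to zero.
#' @param grid a [SuperpixelGrid-class] matching the field dims.
#' @param geneNames gene names when `values` carries none.
#' @return a [HighResExpression-class].
#' @export
HighResExpression <- function(values, mask, grid, geneNames = NULL) {
  if (!is.null(geneNames)) dimnames(values)[[3]] <- geneNames
  mask <- matrix(as.logical(mask), nrow = dim(values)[1])
  for (k in seq_len(dim(values)[3])) values[, , k][!mask] <- 0
  new("HighResExpression", values = values, mask = mask, grid = grid)
}

#' Crop a high-resolution field to a smaller grid
#'
#' Keeps the top-left `nRows` x `nCols` superpixels; used to remove the
#' tile-padding margin after whole-slide inference so predictions align
#' with a ground-truth grid.
#'
#' @param highres a [HighResExpression-class].
#' @param nRows,nCols target dimensions (must not exceed the current ones).
#' @return a [HighResExpression-class].
#' @export
cropHighRes <- function(highres, nRows, nCols) {
  grid <- superpixelGridOf(highres)
  stopifnot(nRows <= grid@nRows, nCols <= grid@nCols)
  vals <- expressionField(highres)[seq_len(nRows), seq_len(nCols), ,
                                   drop = FALSE]
  mask <- validMask(highres)[seq_len(nRows), seq_len(nCols), drop = FALSE]
  HighResExpression(vals, mask,
                    SuperpixelGrid(nRows, nCols,
                                   superpixelUm = grid@superpixelUm,
                                   pixelSizeUm = grid@pixelSizeUm,
                                   originUm = grid@originUm))
}
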
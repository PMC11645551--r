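# Aggregation between cells, superpixels and spots.
#
# Three resolutions are linked here: single cells (imaging-based ST),
# 8 um superpixels (the method's output unit) and 55 um spots (the
# sequencing-based capture unit). Benchmark ground truth is built by
# partitioning cell expression onto the superpixel grid by overlap area;
# pseudo-Visium inputs are built by summing cells (or grid units) under a
# Visium-like spot layout.

#' Partition cell expression onto the superpixel grid by overlap area
#'
#' Each cell's expression vector is split across the superpixels its
#' footprint overlaps, proportionally to the overlap area: superpixel
#' (m, n) receives `sum_k (A_kmn / A_k) * c_k` where `A_kmn` is the exact
#' area of footprint-k intersected with superpixel (m, n). Total expression
#' is conserved for cells whose footprint lies inside the grid. Footprints
#' are axis-aligned boxes (explicit, or squares derived from cell area), so
#' overlaps are exact interval products.
#'
#' @param cells a [CellTable-class].
#' @param grid the target [SuperpixelGrid-class].
#' @param mask optional logical tissue mask for the result (default: all
#'   TRUE; note masking zeroes expression assigned outside it).
#' @return a [HighResExpression-class].
#' @export
cellsToSuperpixels <- function(cells, grid, mask = NULL) {
  fp <- cellFootprints(cells)
  expr <- cellExpression(cells)
  s <- grid@superpixelUm
  ox <- grid@originUm[1]; oy <- grid@originUm[2]
  nR <- grid@nRows; nC <- grid@nCols
  K <- ncol(expr)
  vals <- array(0, dim = c(nR, nC, K), dimnames = list(NULL, NULL, colnames(expr)))
  gx1 <- ox; gx2 <- ox + nC * s; gy1 <- oy; gy2 <- oy + nR * s
  dropped <- 0L
  for (k in seq_len(nrow(fp))) {
    x1 <- fp[k, 1]; y1 <- fp[k, 2]; x2 <- fp[k, 3]; y2 <- fp[k, 4]
    if (x2 <= gx1 || x1 >= gx2 || y2 <= gy1 || y1 >= gy2) {
      dropped <- dropped + 1L
      next
    }
    cLo <- max(1L, floor((x1 - ox) / s) + 1L)
    cHi <- min(nC, ceiling((x2 - ox) / s))
    rLo <- max(1L, floor((y1 - oy) / s) + 1L)
    rHi <- min(nR, ceiling((y2 - oy) / s))
    ccs <- cLo:cHi; rrs <- rLo:rHi
    # exact overlap length of [x1, x2] with each column interval
    wx <- pmax(0, pmin(x2, ox + ccs * s) - pmax(x1, ox + (ccs - 1) * s))
    wy <- pmax(0, pmin(y2, oy + rrs * s) - pmax(y1, oy + (rrs - 1) * s))
    frac <- outer(wy, wx) / cellAreas(cells)[k]
    nz <- which(frac > 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) next
    for (g in seq_len(K)) {
      vals[cbind(rrs[nz[, 1]], ccs[nz[, 2]], g)] <-
        vals[cbind(rrs[nz[, 1]], ccs[nz[, 2]], g)] + frac[nz] * expr[k, g]
    }
  }
  if (dropped > 0L)
    warning(dropped, " cell footprint(s) entirely outside the grid; excluded")
  if (is.null(mask)) mask <- matrix(TRUE, nR, nC)
  HighResExpression(vals, mask, grid)
}

#' Simulate pseudo-Visium spots from a cell table
#'
#' Each spot receives the summed expression of the cells it covers; a cell
#' is covered by a spot when its centroid lies within `diameter/2` of the
#' spot center. When spot discs overlap, a cell counts only toward its
#' nearest covering spot, so each cell contributes to at most one spot.
#'
#' @param cells a [CellTable-class].
#' @param layout the pseudo-spot [SpotLayout-class].
#' @return a [SpotExpression-class].
#' @export
pseudoVisiumFromCells <- function(cells, layout) {
  ctr <- spotCenters(layout)
  if (nrow(ctr) == 0L) stop("layout is empty")
  cen <- cellCentroids(cells)
  expr <- cellExpression(cells)
  r <- spotDiameter(layout) / 2
  counts <- matrix(0, nrow(ctr), ncol(expr),
                   dimnames = list(NULL, colnames(expr)))
  if (nrow(cen) > 0L) {
    d2 <- outer(cen[, 1], ctr[, 1], "-")^2 + outer(cen[, 2], ctr[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    inside <- d2[cbind(seq_len(nrow(cen)), nearest)] <= r^2
    for (j in unique(nearest[inside])) {
      rows <- which(inside & nearest == j)
      counts[j, ] <- colSums(expr[rows, , drop = FALSE])
    }
  }
  SpotExpression(counts, layout)
}

# shared core: sum field values over superpixel centers within spot radius
.aggregateFieldToSpots <- function(highres, layout, warnEmpty = TRUE) {
  grid <- superpixelGridOf(highres)
  ctr <- spotCenters(layout)
  r <- spotDiameter(layout) / 2
  sp <- superpixelCenters(grid)
  vals <- expressionField(highres)
  K <- dim(vals)[3]
  counts <- matrix(0, nrow(ctr), K,
                   dimnames = list(NULL, dimnames(vals)[[3]]))
  flat <- matrix(vals, nrow = grid@nRows * grid@nCols, ncol = K)
  empty <- 0L
  for (j in seq_len(nrow(ctr))) {
    dx2 <- (sp$x - ctr[j, 1])^2
    dy2 <- (sp$y - ctr[j, 2])^2
    cols <- which(dx2 <= r^2)  # candidate columns; exact test below
    hit <- integer(0)
    if (length(cols)) {
      sel <- outer(dy2, dx2[cols], "+") <= r^2
      idx <- which(sel, arr.ind = TRUE)
      if (nrow(idx)) hit <- idx[, 1] + (cols[idx[, 2]] - 1L) * grid@nRows
    }
    if (length(hit) == 0L) empty <- empty + 1L
    else counts[j, ] <- colSums(flat[hit, , drop = FALSE])
  }
  if (warnEmpty && empty > 0L)
    warning(empty, " spot(s) cover no superpixel center; zero rows returned")
  SpotExpression(counts, layout)
}

#' Simulate pseudo-Visium spots from a gapless binned grid
#'
#' Visium-HD-style simulation: a spot's expression is the sum of the grid
#' units whose centers lie within the spot radius of the spot center.
#'
#' @param highres a [HighResExpression-class] (the single-cell-resolution
#'   ground truth).
#' @param layout the pseudo-spot [SpotLayout-class], in the same physical
#'   frame as the grid.
#' @return a [SpotExpression-class].
#' @export
pseudoVisiumFromBins <- function(highres, layout) {
  .aggregateFieldToSpots(highres, layout)
}

#' Re-aggregate a predicted field to observed spot positions
#'
#' Evaluation path for spot-only datasets: sums predicted superpixel
#' expression under each observed spot so predictions can be scored against
#' the measured spot values. Identical arithmetic to
#' [pseudoVisiumFromBins()] with externally supplied centers.
#'
#' @param pred a predicted [HighResExpression-class].
#' @param layout the observed [SpotLayout-class].
#' @return a [SpotExpression-class].
#' @export
reaggregateToSpots <- function(pred, layout) {
  .aggregateFieldToSpots(pred, layout)
}

#' Select the top highly variable genes
#'
#' Ranks genes by the variance of library-size-normalised,
#' log1p-transformed counts (each spot scaled to the mean library size) and
#' keeps the top `n`. Ties are broken by gene name so selection is
#' deterministic.
#'
#' @param spotExpr a [SpotExpression-class].
#' @param n number of genes to keep (default 1000).
#' @return a [SpotExpression-class] restricted to the selected genes, in
#'   decreasing dispersion order.
#' @export
selectHVG <- function(spotExpr, n = 1000) {
  counts <- spotCounts(spotExpr)
  if (n > ncol(counts))
    stop("n (", n, ") exceeds the number of genes (", ncol(counts), ")")
  lib <- rowSums(counts)
  sf <- lib / mean(lib[lib > 0])
  sf[sf == 0] <- 1
  norm <- log1p(counts / sf)
  v <- apply(norm, 2, stats::var)
  ord <- order(-v, colnames(counts))
  keep <- ord[seq_len(n)]
  SpotExpression(counts[, keep, drop = FALSE], spotLayout(spotExpr))
}

#' Uniform-disaggregation baseline field
#'
#' The naive super-resolution baseline: each spot's expression is spread
#' equally over the superpixels whose centers fall inside its disc;
#' superpixels covered by no spot stay zero. Used as the reference the
#' trained model must beat.
#'
#' @param spotExpr a [SpotExpression-class].
#' @param grid the output [SuperpixelGrid-class].
#' @param mask optional logical tissue mask.
#' @return a [HighResExpression-class].
#' @export
uniformDisaggregation <- function(spotExpr, grid, mask = NULL) {
  layout <- spotLayout(spotExpr)
  ctr <- spotCenters(layout)
  r <- spotDiameter(layout) / 2
  sp <- superpixelCenters(grid)
  counts <- spotCounts(spotExpr)
  K <- ncol(counts)
  vals <- array(0, dim = c(grid@nRows, grid@nCols, K),
                dimnames = list(NULL, NULL, colnames(counts)))
  flat <- matrix(0, grid@nRows * grid@nCols, K)
  for (j in seq_len(nrow(ctr))) {
    sel <- outer((sp$y - ctr[j, 2])^2, (sp$x - ctr[j, 1])^2, "+") <= r^2
    nin <- sum(sel)
    if (nin > 0)
      flat[which(sel), ] <- flat[which(sel), , drop = FALSE] +
        matrix(counts[j, ] / nin, nin, K, byrow = TRUE)
  }
  vals[] <- flat
  if (is.null(mask)) mask <- matrix(TRUE, grid@nRows, grid@nCols)
  HighResExpression(vals, mask, grid)
}
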
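# Readers and writers for the standard on-disk formats.

#' Read spot-level expression with geometry
#'
#' Counts come either from a matrix-market triplet (`.mtx` plus barcode and
#' feature text files, 10x layout: features x spots) or from a CSV with one
#' row per spot, a `barcode` first column and gene names in the header.
#' Positions use the 10x tissue-positions dialect: columns `barcode`,
#' `row`, `col`, `x_px`, `y_px`. Pixel coordinates are converted to
#' micrometres via `geometry$pixel_size_um`.
#'
#' @param countsPath path to `.mtx` or `.csv` counts.
#' @param positionsPath path to the positions CSV.
#' @param geometry list (or path to a JSON file) with `pixel_size_um`,
#'   `spot_diameter_um`, `spot_pitch_um`.
#' @param barcodesPath,featuresPath companions of an `.mtx` file (defaults:
#'   `barcodes.tsv` / `features.tsv` next to it).
#' @return a [SpotExpression-class]; spots ordered as in the positions
#'   table.
#' @export
readSpotData <- function(countsPath, positionsPath, geometry,
                         barcodesPath = NULL, featuresPath = NULL) {
  if (is.character(geometry)) geometry <- jsonlite::read_json(geometry)
  pos <- utils::read.csv(positionsPath, stringsAsFactors = FALSE)
  need <- c("barcode", "row", "col", "x_px", "y_px")
  if (!all(need %in% names(pos)))
    stop("positions table must have columns: ", paste(need, collapse = ", "))
  if (grepl("\\.mtx$", countsPath)) {
    if (is.null(barcodesPath))
      barcodesPath <- file.path(dirname(countsPath), "barcodes.tsv")
    if (is.null(featuresPath))
      featuresPath <- file.path(dirname(countsPath), "features.tsv")
    m <- as.matrix(Matrix::readMM(countsPath))
    barcodes <- readLines(barcodesPath)
    features <- utils::read.delim(featuresPath, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(features) || ncol(m) != length(barcodes))
      stop(sprintf("matrix is %d x %d but features/barcodes have %d / %d entries",
                   nrow(m), ncol(m), length(features), length(barcodes)))
    counts <- t(m)
    dimnames(counts) <- list(barcodes, features)
  } else {
    df <- utils::read.csv(countsPath, stringsAsFactors = FALSE,
                          check.names = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
  }
  if (nrow(counts) != nrow(pos) || !setequal(rownames(counts), pos$barcode))
    stop(sprintf("counts have %d barcodes but positions list %d (or names differ)",
                 nrow(counts), nrow(pos)))
  counts <- counts[pos$barcode, , drop = FALSE]
  px <- geometry$pixel_size_um
  centers <- cbind(x = pos$x_px * px, y = pos$y_px * px)
  layout <- SpotLayout(centers, geometry$spot_diameter_um,
                       geometry$spot_pitch_um)
  SpotExpression(counts, layout)
}

#' Read a cell table
#'
#' `cellsPath`: CSV with columns `cell_id`, `x_um`, `y_um`, `area_um2`.
#' `exprPath`: CSV, one row per cell, `cell_id` first column, gene names in
#' the header. Rows are matched by cell id.
#'
#' @param cellsPath,exprPath file paths.
#' @return a [CellTable-class].
#' @export
readCellTable <- function(cellsPath, exprPath) {
  cells <- utils::read.csv(cellsPath, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_um", "y_um", "area_um2")
  if (!all(need %in% names(cells)))
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  ex <- utils::read.csv(exprPath, stringsAsFactors = FALSE,
                        check.names = FALSE)
  expr <- as.matrix(ex[, -1, drop = FALSE])
  rownames(expr) <- ex[[1]]
  if (nrow(expr) != nrow(cells) || !setequal(rownames(expr), cells$cell_id))
    stop(sprintf("expression has %d cells but table lists %d (or ids differ)",
                 nrow(expr), nrow(cells)))
  expr <- expr[as.character(cells$cell_id), , drop = FALSE]
  CellTable(expr, cbind(cells$x_um, cells$y_um), cells$area_um2)
}

#' Write / read a HighResExpression HDF5 container
#'
#' Datasets: `values` (rows x cols x genes), `mask` (uint8), `gene_names`;
#' attributes `superpixel_um`, `pixel_size_um`, `origin_um` on the root.
#' Values are stored at full double precision so a write-read round trip
#' reproduces the object exactly.
#'
#' @param path output `.h5` path (overwritten).
#' @param highres a [HighResExpression-class].
#' @return `writeHighRes` returns `path` invisibly; `readHighRes` the
#'   reconstructed object.
#' @export
writeHighRes <- function(path, highres) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(expressionField(highres), path, "values")
  rhdf5::h5write(validMask(highres) * 1L, path, "mask")
  rhdf5::h5write(geneNames(highres), path, "gene_names")
  grid <- superpixelGridOf(highres)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(grid@superpixelUm, fid, "superpixel_um")
  rhdf5::h5writeAttribute(grid@pixelSizeUm, fid, "pixel_size_um")
  rhdf5::h5writeAttribute(grid@originUm, fid, "origin_um")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname writeHighRes
#' @export
readHighRes <- function(path) {
  vals <- rhdf5::h5read(path, "values")
  mask <- rhdf5::h5read(path, "mask") > 0
  genes <- as.character(rhdf5::h5read(path, "gene_names"))
  fid <- rhdf5::H5Fopen(path)
  su <- as.numeric(rhdf5::h5readAttributes(fid, "/")$superpixel_um)
  px <- as.numeric(rhdf5::h5readAttributes(fid, "/")$pixel_size_um)
  org <- as.numeric(rhdf5::h5readAttributes(fid, "/")$origin_um)
  rhdf5::H5Fclose(fid)
  grid <- SuperpixelGrid(dim(vals)[1], dim(vals)[2], superpixelUm = su,
                         pixelSizeUm = px, originUm = org)
  HighResExpression(vals, mask, grid, geneNames = genes)
}

#' Write spot expression as CSV pair
#'
#' Companion writer for simulated data: `<prefix>_counts.csv` (barcode +
#' genes) and `<prefix>_positions.csv` (10x tissue-positions dialect) plus
#' `<prefix>_geometry.json`.
#'
#' @param prefix output path prefix.
#' @param spotExpr a [SpotExpression-class].
#' @param pixelSizeUm pixel size used to express centers in pixels.
#' @return invisibly, the three paths written.
#' @export
writeSpotData <- function(prefix, spotExpr, pixelSizeUm = 0.5) {
  counts <- spotCounts(spotExpr)
  layout <- spotLayout(spotExpr)
  barcodes <- sprintf("spot%04d", seq_len(nrow(counts)))
  cpath <- paste0(prefix, "_counts.csv")
  utils::write.csv(data.frame(barcode = barcodes, counts,
                              check.names = FALSE),
                   cpath, row.names = FALSE)
  ctr <- spotCenters(layout)
  ppath <- paste0(prefix, "_positions.csv")
  utils::write.csv(data.frame(barcode = barcodes,
                              row = seq_len(nrow(ctr)), col = 1L,
                              x_px = ctr[, 1] / pixelSizeUm,
                              y_px = ctr[, 2] / pixelSizeUm),
                   ppath, row.names = FALSE)
  gpath <- paste0(prefix, "_geometry.json")
  jsonlite::write_json(list(pixel_size_um = pixelSizeUm,
                            spot_diameter_um = spotDiameter(layout),
                            spot_pitch_um = spotPitch(layout)),
                       gpath, auto_unbox = TRUE, digits = NA)
  invisible(c(cpath, ppath, gpath))
}

#' Read an RGB image (PNG or TIFF)
#'
#' @param path image path; format chosen by extension.
#' @return rows x cols x 3 array in [0, 1].
#' @export
readImage <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
           tiff::readTIFF(path)
         else stop("unsupported image format (PNG or TIFF): ", path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write / read a multimodal feature-map cache
#'
#' HDF5 container with datasets `channels` (rows x cols x C),
#' `channel_roles`, `mask` (uint8) and grid attributes; lets the expensive
#' featurisation step be cached between training and inference runs.
#'
#' @param path `.h5` path (overwritten on write).
#' @param featureMap a [MultimodalFeatureMap-class].
#' @param mask logical tissue mask saved alongside the channels.
#' @return `writeFeatureMap` returns `path` invisibly; `readFeatureMap` a
#'   list with `featureMap` and `mask`.
#' @export
writeFeatureMap <- function(path, featureMap, mask) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(featureChannels(featureMap), path, "channels")
  rhdf5::h5write(channelRoles(featureMap), path, "channel_roles")
  rhdf5::h5write(mask * 1L, path, "mask")
  grid <- superpixelGridOf(featureMap)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(grid@superpixelUm, fid, "superpixel_um")
  rhdf5::h5writeAttribute(grid@pixelSizeUm, fid, "pixel_size_um")
  rhdf5::h5writeAttribute(grid@originUm, fid, "origin_um")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname writeFeatureMap
#' @export
readFeatureMap <- function(path) {
  ch <- rhdf5::h5read(path, "channels")
  roles <- as.character(rhdf5::h5read(path, "channel_roles"))
  mask <- rhdf5::h5read(path, "mask") > 0
  fid <- rhdf5::H5Fopen(path)
  at <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  grid <- SuperpixelGrid(dim(ch)[1], dim(ch)[2],
                         superpixelUm = as.numeric(at$superpixel_um),
                         pixelSizeUm = as.numeric(at$pixel_size_um),
                         originUm = as.numeric(at$origin_um))
  list(featureMap = new("MultimodalFeatureMap", channels = ch,
                        channelRoles = roles, grid = grid),
       mask = matrix(mask, dim(ch)[1], dim(ch)[2]))
}

#' Save / load a trained model
#'
#' Versioned serialisation of the weight arrays, gene names and seed.
#'
#' @param path output path.
#' @param model a [SuperResModel-class].
#' @return `saveModel` returns `path` invisibly; `loadModel` the model.
#' @export
saveModel <- function(path, model) {
  obj <- list(format = "supergrid-model", version = 1L,
              W0 = model@W0, W1 = model@W1, W2 = model@W2, b = model@b,
              hiddenDim = model@hiddenDim, geneNames = model@geneNames,
              seed = model@seed)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "supergrid-model"))
    stop("not a supergrid model file: ", path)
  new("SuperResModel", W0 = obj$W0, W1 = obj$W1, W2 = obj$W2, b = obj$b,
      hiddenDim = obj$hiddenDim, geneNames = obj$geneNames, seed = obj$seed)
}
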
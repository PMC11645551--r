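# Accessor generics. Slot access stays internal to the package.

#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))
#' @export
setGeneric("spotCounts", function(object) standardGeneric("spotCounts"))
#' @export
setGeneric("spotCenters", function(object) standardGeneric("spotCenters"))
#' @export
setGeneric("spotDiameter", function(object) standardGeneric("spotDiameter"))
#' @export
setGeneric("spotPitch", function(object) standardGeneric("spotPitch"))
#' @export
setGeneric("spotLayout", function(object) standardGeneric("spotLayout"))
#' @export
setGeneric("expressionField", function(object) standardGeneric("expressionField"))
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @export
setGeneric("superpixelGridOf", function(object) standardGeneric("superpixelGridOf"))
#' @export
setGeneric("featureChannels", function(object) standardGeneric("featureChannels"))
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))
#' @export
setGeneric("cellExpression", function(object) standardGeneric("cellExpression"))
#' @export
setGeneric("cellCentroids", function(object) standardGeneric("cellCentroids"))
#' @export
setGeneric("cellAreas", function(object) standardGeneric("cellAreas"))
#' @export
setGeneric("cellFootprints", function(object) standardGeneric("cellFootprints"))
#' @export
setGeneric("perGeneMetrics", function(object) standardGeneric("perGeneMetrics"))
#' @export
setGeneric("metricSummary", function(object) standardGeneric("metricSummary"))

#' @describeIn SpotExpression-class gene names (column names of the counts).
#' @param object a supergrid S4 object.
#' @export
setMethod("geneNames", "SpotExpression", function(object) colnames(object@counts))
#' @describeIn HighResExpression-class gene names of the field.
#' @export
setMethod("geneNames", "HighResExpression",
          function(object) dimnames(object@values)[[3]])
#' @describeIn CellTable-class gene names of the cell expression matrix.
#' @export
setMethod("geneNames", "CellTable", function(object) colnames(object@expression))

#' @describeIn SpotExpression-class the spots x genes count matrix.
#' @export
setMethod("spotCounts", "SpotExpression", function(object) object@counts)
#' @describeIn SpotExpression-class the layout the counts are attached to.
#' @export
setMethod("spotLayout", "SpotExpression", function(object) object@layout)
#' @describeIn SpotLayout-class spot centers (um), spots x 2.
#' @export
setMethod("spotCenters", "SpotLayout", function(object) object@centersUm)
#' @export
setMethod("spotCenters", "SpotExpression",
          function(object) object@layout@centersUm)
#' @describeIn SpotLayout-class spot diameter (um).
#' @export
setMethod("spotDiameter", "SpotLayout", function(object) object@diameterUm)
#' @export
setMethod("spotDiameter", "SpotExpression",
          function(object) object@layout@diameterUm)
#' @describeIn SpotLayout-class center-to-center pitch (um).
#' @export
setMethod("spotPitch", "SpotLayout", function(object) object@pitchUm)

#' @describeIn HighResExpression-class the rows x cols x genes array.
#' @export
setMethod("expressionField", "HighResExpression", function(object) object@values)
#' @describeIn HighResExpression-class the logical tissue mask.
#' @export
setMethod("validMask", "HighResExpression", function(object) object@mask)
#' @describeIn HighResExpression-class the underlying superpixel grid.
#' @export
setMethod("superpixelGridOf", "HighResExpression", function(object) object@grid)
#' @export
setMethod("superpixelGridOf", "MultimodalFeatureMap", function(object) object@grid)

#' @describeIn MultimodalFeatureMap-class the rows x cols x C channel array.
#' @export
setMethod("featureChannels", "MultimodalFeatureMap",
          function(object) object@channels)
#' @describeIn MultimodalFeatureMap-class per-channel role tags.
#' @export
setMethod("channelRoles", "MultimodalFeatureMap",
          function(object) object@channelRoles)

#' @describeIn CellTable-class the cells x genes expression matrix.
#' @export
setMethod("cellExpression", "CellTable", function(object) object@expression)
#' @describeIn CellTable-class cell centroids (um), cells x 2.
#' @export
setMethod("cellCentroids", "CellTable", function(object) object@centroidsUm)
#' @describeIn CellTable-class per-cell areas (um^2).
#' @export
setMethod("cellAreas", "CellTable", function(object) object@areasUm2)
#' @describeIn CellTable-class footprint boxes (xmin, ymin, xmax, ymax); a
#'   square of the stated area is synthesised when none were supplied.
#' @export
setMethod("cellFootprints", "CellTable", function(object) {
  fp <- object@footprints
  if (nrow(fp) == 0L && nrow(object@centroidsUm) > 0L) {
    half <- sqrt(object@areasUm2) / 2
    fp <- cbind(object@centroidsUm[, 1] - half, object@centroidsUm[, 2] - half,
                object@centroidsUm[, 1] + half, object@centroidsUm[, 2] + half)
  }
  colnames(fp) <- c("xmin", "ymin", "xmax", "ymax")
  fp
})

#' @describeIn GeneMetrics-class the per-gene metric table.
#' @export
setMethod("perGeneMetrics", "GeneMetrics", function(object) object@perGene)
#' @describeIn GeneMetrics-class median/mean summaries over scored genes.
#' @export
setMethod("metricSummary", "GeneMetrics", function(object) object@summary)

setMethod("show", "SuperpixelGrid", function(object) {
  cat(sprintf("SuperpixelGrid: %d x %d superpixels of %g um (%g um/px)\n",
              object@nRows, object@nCols, object@superpixelUm,
              object@pixelSizeUm))
})

setMethod("show", "SpotLayout", function(object) {
  cat(sprintf("SpotLayout: %d spots, diameter %g um, pitch %g um (%s lattice)\n",
              nrow(object@centersUm), object@diameterUm, object@pitchUm,
              object@lattice))
})

setMethod("show", "SpotExpression", function(object) {
  cat(sprintf("SpotExpression: %d spots x %d genes\n",
              nrow(object@counts), ncol(object@counts)))
  show(object@layout)
})

setMethod("show", "CellTable", function(object) {
  cat(sprintf("CellTable: %d cells x %d genes (%s footprints)\n",
              nrow(object@expression), ncol(object@expression),
              if (nrow(object@footprints)) "explicit box" else "square-from-area"))
})

setMethod("show", "HighResExpression", function(object) {
  cat(sprintf("HighResExpression: %d x %d x %d genes, %d/%d superpixels in tissue\n",
              dim(object@values)[1], dim(object@values)[2],
              dim(object@values)[3], sum(object@mask), length(object@mask)))
})

setMethod("show", "MultimodalFeatureMap", function(object) {
  tab <- table(factor(object@channelRoles,
                      levels = c("hist", "pos_y", "pos_x",
                                 "rgb_r", "rgb_g", "rgb_b")))
  cat(sprintf("MultimodalFeatureMap: %d x %d x %d channels (hist %d + pos 2 + rgb 3)\n",
              dim(object@channels)[1], dim(object@channels)[2],
              dim(object@channels)[3], tab[["hist"]]))
})

setMethod("show", "SuperResModel", function(object) {
  cat(sprintf("SuperResModel: C=%d -> %d -> %d -> K=%d genes (elu+1 output)\n",
              nrow(object@W0), object@hiddenDim, object@hiddenDim,
              ncol(object@W2)))
})

setMethod("show", "GeneMetrics", function(object) {
  cat(sprintf("GeneMetrics over %d genes (%d flagged constant)\n",
              nrow(object@perGene), sum(object@perGene$constant)))
  print(object@summary)
})
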
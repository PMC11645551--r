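# End-to-end convenience wrapper.

#' Train and infer super-resolution expression from image + spots
#'
#' The full pipeline on one section: build the multimodal feature map from
#' the histology image, cut per-spot training patches, train the GCN under
#' weak supervision and infer the whole-slide superpixel expression field.
#'
#' @param image RGB array (or [PreparedImage-class]) of the H&E section.
#' @param spotExpr observed [SpotExpression-class].
#' @param sourcePixelSizeUm pixel size of `image`.
#' @param backbone a [HistologyBackbone-class]
#'   (default [fallbackBackbone()]).
#' @param config a [TrainConfig-class].
#' @param mask optional tissue mask overriding the detected one.
#' @param verbose print training progress.
#' @return list with `highres` ([HighResExpression-class]), `model`,
#'   `graph`, `featureMap`, `mask`, `lossHistory`.
#' @export
superResolve <- function(image, spotExpr, sourcePixelSizeUm = 0.5,
                         backbone = fallbackBackbone(),
                         config = trainConfig(), mask = NULL,
                         verbose = FALSE) {
  fm <- buildFeatureMap(image, sourcePixelSizeUm, backbone)
  if (is.null(mask)) mask <- fm$mask
  grid <- superpixelGridOf(fm$featureMap)
  D <- computePatchSpan(spotDiameter(spotExpr), grid@superpixelUm)
  graph <- buildAdjacency(D)
  patches <- buildSpotPatches(fm$featureMap, spotExpr, D)
  fit <- trainSuperRes(patches, graph, config, verbose = verbose)
  highres <- inferSuperRes(fm$featureMap, fit$model, graph, mask)
  list(highres = highres, model = fit$model, graph = graph,
       featureMap = fm$featureMap, mask = mask,
       lossHistory = fit$lossHistory)
}
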
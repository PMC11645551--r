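# Gene-wise evaluation of predicted expression fields.
#
# Metrics are computed per gene on min-max normalised 2-D maps (RMSE, MAE,
# SSIM) over in-mask superpixels; Pearson correlation is scale-free and
# computed on the raw masked values. Spot-level scoring re-aggregates the
# predicted field under the observed spots first.

#' Min-max normalise a gene map over the mask
#'
#' `(x - min) / (max - min)` with min/max taken over masked entries; makes
#' RMSE/MAE/SSIM scale-free across genes. Constant maps normalise to all
#' zeros and carry a `constant = TRUE` attribute so downstream metrics can
#' flag them.
#'
#' @param map numeric matrix.
#' @param mask logical matrix (default: all TRUE).
#' @return normalised matrix with attribute `constant`.
#' @export
normalizeGeneMap <- function(map, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map), ncol(map))
  v <- map[mask]
  if (length(v) == 0L) stop("empty mask")
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-12) {
    out <- map * 0
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (map - lo) / (hi - lo)
  attr(out, "constant") <- FALSE
  out
}

#' @rdname geneMetricsOps
#' @export
geneRMSE <- function(pred, truth, mask = NULL) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (is.null(mask)) mask <- !is.na(pred) & TRUE
  if (!any(mask)) stop("empty mask")
  sqrt(mean((pred[mask] - truth[mask])^2))
}

#' @rdname geneMetricsOps
#' @export
geneMAE <- function(pred, truth, mask = NULL) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (is.null(mask)) mask <- !is.na(pred) & TRUE
  if (!any(mask)) stop("empty mask")
  mean(abs(pred[mask] - truth[mask]))
}

#' Scalar gene-map metrics
#'
#' `geneRMSE`, `geneMAE` and `genePCC` score two 2-D gene maps over masked
#' entries. PCC is undefined (NA) when either map has zero variance on the
#' mask.
#'
#' @param pred,truth numeric matrices of equal shape.
#' @param mask logical matrix; metrics use masked entries only.
#' @return scalar.
#' @name geneMetricsOps
#' @export
genePCC <- function(pred, truth, mask = NULL) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (is.null(mask)) mask <- !is.na(pred) & TRUE
  if (!any(mask)) stop("empty mask")
  a <- pred[mask]; b <- truth[mask]
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  stats::cor(a, b)
}

#' Structural similarity between two gene maps
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03 and data range 1 (maps are expected min-max normalised).
#' Local statistics use reflection padding at the borders; the SSIM map is
#' averaged over masked window centers.
#'
#' @param pred,truth numeric matrices in [0, 1] of equal shape.
#' @param mask logical matrix of window centers to average over.
#' @param windowSize,sigma Gaussian window parameters.
#' @param K1,K2,dataRange SSIM stabilisation constants.
#' @return scalar in [-1, 1].
#' @export
geneSSIM <- function(pred, truth, mask = NULL, windowSize = 11L, sigma = 1.5,
                     K1 = 0.01, K2 = 0.03, dataRange = 1) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pred), ncol(pred))
  if (!any(mask)) stop("empty mask")
  k <- .gaussianKernel(windowSize, sigma)
  C1 <- (K1 * dataRange)^2; C2 <- (K2 * dataRange)^2
  mu1 <- .conv2Reflect(pred, k); mu2 <- .conv2Reflect(truth, k)
  s11 <- .conv2Reflect(pred^2, k) - mu1^2
  s22 <- .conv2Reflect(truth^2, k) - mu2^2
  s12 <- .conv2Reflect(pred * truth, k) - mu1 * mu2
  ssimMap <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssimMap[mask])
}

.summarise <- function(perGene) {
  ok <- !perGene$constant
  mcols <- c("rmse", "ssim", "pcc", "mae")
  med <- vapply(mcols, function(m) stats::median(perGene[[m]][ok], na.rm = TRUE),
                numeric(1))
  mea <- vapply(mcols, function(m) mean(perGene[[m]][ok], na.rm = TRUE),
                numeric(1))
  data.frame(stat = c("median", "mean"), rbind(med, mea), row.names = NULL)
}

#' Gene-wise evaluation of a predicted field against ground truth
#'
#' For each gene, both 2-D maps are min-max normalised over the shared
#' tissue mask, then RMSE, SSIM, MAE (on normalised maps) and Pearson
#' correlation (scale-free, on raw masked values) are computed. Genes whose
#' truth map is constant on the mask are flagged and excluded from the
#' summary statistics.
#'
#' @param pred,truth [HighResExpression-class] objects on the same grid;
#'   genes are matched by name (intersection, truth order).
#' @return a [GeneMetrics-class].
#' @export
evaluateHighRes <- function(pred, truth) {
  if (!identical(dim(expressionField(pred))[1:2],
                 dim(expressionField(truth))[1:2]))
    stop("pred and truth grids disagree")
  genes <- intersect(geneNames(truth), geneNames(pred))
  if (length(genes) == 0L) stop("no shared genes")
  mask <- validMask(truth) & validMask(pred)
  pv <- expressionField(pred); tv <- expressionField(truth)
  rows <- lapply(genes, function(g) {
    p <- pv[, , g]; t_ <- tv[, , g]
    pn <- normalizeGeneMap(p, mask); tn <- normalizeGeneMap(t_, mask)
    constant <- attr(tn, "constant") || attr(pn, "constant")
    data.frame(gene = g,
               rmse = geneRMSE(pn, tn, mask),
               ssim = geneSSIM(pn, tn, mask),
               pcc = genePCC(p, t_, mask),
               mae = geneMAE(pn, tn, mask),
               constant = constant)
  })
  perGene <- do.call(rbind, rows)
  new("GeneMetrics", perGene = perGene, summary = .summarise(perGene))
}

#' Spot-level evaluation of a predicted field
#'
#' Re-aggregates the predicted field under the observed spot layout
#' ([reaggregateToSpots()]) and scores the per-gene spot vectors (min-max
#' normalised RMSE and MAE, raw-scale PCC; SSIM is not defined for 1-D spot
#' vectors and reported as NA).
#'
#' @param pred a [HighResExpression-class].
#' @param observed the observed [SpotExpression-class].
#' @return a [GeneMetrics-class].
#' @export
evaluateAtSpots <- function(pred, observed) {
  agg <- reaggregateToSpots(pred, spotLayout(observed))
  genes <- intersect(geneNames(observed), geneNames(agg))
  if (length(genes) == 0L) stop("no shared genes")
  pm <- spotCounts(agg); om <- spotCounts(observed)
  norm1d <- function(x) {
    if (max(x) - min(x) < 1e-12) return(structure(x * 0, constant = TRUE))
    structure((x - min(x)) / (max(x) - min(x)), constant = FALSE)
  }
  rows <- lapply(genes, function(g) {
    p <- pm[, g]; o <- om[, g]
    pn <- norm1d(p); on_ <- norm1d(o)
    data.frame(gene = g,
               rmse = sqrt(mean((pn - on_)^2)),
               ssim = NA_real_,
               pcc = if (stats::sd(p) < 1e-12 || stats::sd(o) < 1e-12)
                 NA_real_ else stats::cor(p, o),
               mae = mean(abs(pn - on_)),
               constant = attr(on_, "constant") || attr(pn, "constant"))
  })
  perGene <- do.call(rbind, rows)
  new("GeneMetrics", perGene = perGene, summary = .summarise(perGene))
}

#' Tertiary lymphoid structure score map
#'
#' Normalises each marker gene's expression map to [0, 1] over the tissue
#' mask and averages across markers, giving a per-superpixel TLS score.
#' Markers missing from the field are skipped with a warning.
#'
#' @param highres a [HighResExpression-class].
#' @param markerGenes character vector of marker gene names.
#' @return numeric matrix (rows x cols); zero outside the mask.
#' @export
tlsScore <- function(highres, markerGenes) {
  genes <- intersect(markerGenes, geneNames(highres))
  missing <- setdiff(markerGenes, genes)
  if (length(missing))
    warning("marker gene(s) not in the field, skipped: ",
            paste(missing, collapse = ", "))
  if (length(genes) == 0L) stop("no marker genes present")
  mask <- validMask(highres)
  vals <- expressionField(highres)
  acc <- matrix(0, nrow(mask), ncol(mask))
  for (g in genes) acc <- acc + normalizeGeneMap(vals[, , g], mask)
  score <- acc / length(genes)
  score[!mask] <- 0
  score
}

#' Tissue segmentation by k-means on GCN features
#'
#' Clusters the masked per-superpixel GCN feature vectors with k-means
#' (k-means++-style multi-restart via `nstart = 10`, fixed seed) and
#' relabels clusters by decreasing size so labels are deterministic.
#'
#' @param gcnFeatures array (rows, cols, F) from [exportGcnFeatures()].
#' @param mask logical tissue mask.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return integer matrix (rows x cols); labels 1..k inside the mask, NA
#'   outside.
#' @export
segmentTissue <- function(gcnFeatures, mask, k, seed = 0, nstart = 10) {
  d <- dim(gcnFeatures)
  X <- matrix(gcnFeatures, d[1] * d[2], d[3])[as.vector(mask), , drop = FALSE]
  labels <- matrix(NA_integer_, d[1], d[2])
  if (k == 1L) {
    labels[mask] <- 1L
    return(labels)
  }
  km <- withSeed(seed,
    stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100))
  sizes <- tabulate(km$cluster, nbins = k)
  relabel <- integer(k)
  relabel[order(-sizes, seq_len(k))] <- seq_len(k)
  labels[mask] <- relabel[km$cluster]
  labels
}

#' Adjusted Rand index between two label maps
#'
#' Compares two clusterings over their shared non-NA support.
#'
#' @param a,b integer label vectors or matrices.
#' @return scalar ARI.
#' @export
adjustedRandIndex <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumij <- sum(comb2(tab))
  sumi <- sum(comb2(rowSums(tab)))
  sumj <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sumi * sumj / comb2(n)
  maxidx <- (sumi + sumj) / 2
  if (abs(maxidx - expected) < 1e-12) return(1)
  (sumij - expected) / (maxidx - expected)
}
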
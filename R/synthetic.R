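# Synthetic benchmark generator.
#
# Emulates the statistical structure the method relies on: a small set of
# smooth latent spatial factors drives both gene expression (through
# non-negative per-gene loadings and Poisson counting noise) and the
# histology image (each factor stains the rendered tissue a distinct
# colour), so image features are informative of expression. Ground truth
# lives on the superpixel grid; pseudo-Visium spots are simulated from it
# by disc aggregation, exactly the protocol used with real single-cell-
# resolution data.

#' Synthetic benchmark configuration
#'
#' Defaults describe the desk-scale benchmark: a 96 x 96 superpixel grid
#' (768 x 768 um), 25 genes driven by 3 latent factors, Poisson counting
#' noise, and per-gene peak mean counts of 10-30 per superpixel (marker-
#' gene scale of imaging panels).
#'
#' @param nRows,nCols grid dimensions in superpixels (default 96 x 96).
#' @param nGenes number of genes (default 25).
#' @param nFactors number of latent factors (default 3).
#' @param patterns pattern families cycled across factors.
#' @param noiseModel "poisson" (default) or "gaussian".
#' @param noiseScale relative sd for gaussian noise (default 0.1).
#' @param textureAmplitude image pixel noise amplitude (default 0.05).
#' @param depthRange per-gene peak mean counts per superpixel.
#' @param seed master seed fixing every draw (default 0).
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nRows = 96, nCols = 96, nGenes = 25,
                            nFactors = 3,
                            patterns = c("gaussian_blob", "stripe",
                                         "gradient", "ring"),
                            noiseModel = c("poisson", "gaussian"),
                            noiseScale = 0.1, textureAmplitude = 0.05,
                            depthRange = c(10, 30), seed = 0) {
  new("SyntheticConfig", nRows = as.integer(nRows), nCols = as.integer(nCols),
      nGenes = as.integer(nGenes), nFactors = as.integer(nFactors),
      patterns = patterns, noiseModel = match.arg(noiseModel),
      noiseScale = noiseScale, textureAmplitude = textureAmplitude,
      depthRange = as.numeric(depthRange), seed = as.integer(seed))
}

# inscribed ellipse mask
.ellipseMask <- function(nR, nC) {
  cy <- (nR + 1) / 2; cx <- (nC + 1) / 2
  ry <- nR / 2 - 0.5; rx <- nC / 2 - 0.5
  outer(seq_len(nR), seq_len(nC),
        function(i, j) ((i - cy) / ry)^2 + ((j - cx) / rx)^2 <= 1)
}

#' Generate the latent spatial factor fields
#'
#' Each factor is a smooth non-negative pattern from the configured family
#' (Gaussian blob, vertical stripe band, linear gradient, ring), normalised
#' to max 1. Pattern placement is seeded and deterministic.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return numeric array (nRows, nCols, nFactors), values in [0, 1].
#' @export
generateLatentFields <- function(cfg) {
  nR <- cfg@nRows; nC <- cfg@nCols
  ii <- matrix(seq_len(nR), nR, nC)
  jj <- matrix(seq_len(nC), nR, nC, byrow = TRUE)
  minDim <- min(nR, nC)
  withSeed(cfg@seed + 101L, {
    out <- array(0, dim = c(nR, nC, cfg@nFactors))
    for (f in seq_len(cfg@nFactors)) {
      pat <- cfg@patterns[(f - 1L) %% length(cfg@patterns) + 1L]
      field <- switch(pat,
        gaussian_blob = {
          cy <- stats::runif(1, 0.3, 0.7) * nR
          cx <- stats::runif(1, 0.3, 0.7) * nC
          s <- minDim / 6
          exp(-((ii - cy)^2 + (jj - cx)^2) / (2 * s^2))
        },
        stripe = {
          c0 <- stats::runif(1, 0.25, 0.75) * nC
          w <- minDim / 8
          exp(-(jj - c0)^2 / (2 * w^2))  # constant along rows
        },
        gradient = {
          th <- stats::runif(1, 0, 2 * pi)
          g <- cos(th) * ii / nR + sin(th) * jj / nC
          g - min(g)
        },
        ring = {
          cy <- stats::runif(1, 0.4, 0.6) * nR
          cx <- stats::runif(1, 0.4, 0.6) * nC
          r0 <- stats::runif(1, 0.25, 0.35) * minDim
          w <- minDim / 12
          d <- sqrt((ii - cy)^2 + (jj - cx)^2)
          exp(-(d - r0)^2 / (2 * w^2))
        },
        stop("unknown pattern: ", pat))
      out[, , f] <- field / max(field)
    }
    out
  })
}

# seeded per-gene loadings (rows sum to 1) and depths
.geneLoadings <- function(cfg) {
  withSeed(cfg@seed + 202L, {
    L <- matrix(stats::rgamma(cfg@nGenes * cfg@nFactors, shape = 1),
                cfg@nGenes, cfg@nFactors)
    L <- L / rowSums(L)
    depth <- stats::runif(cfg@nGenes, cfg@depthRange[1], cfg@depthRange[2])
    list(loadings = L, depth = depth)
  })
}

#' Generate the ground-truth high-resolution expression field
#'
#' Gene g's mean field is a non-negative mixture of the latent fields
#' (seeded loadings summing to 1) scaled by a seeded per-gene depth; the
#' observed field adds Poisson counting noise (or truncated Gaussian noise
#' with relative sd `noiseScale`). The tissue mask is the ellipse inscribed
#' in the grid; values outside are zero.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param latentFields optional precomputed [generateLatentFields()] output.
#' @return a [HighResExpression-class] with attribute `meanField` (the
#'   noise-free array) for reference.
#' @export
generateGroundTruth <- function(cfg, latentFields = generateLatentFields(cfg)) {
  nR <- cfg@nRows; nC <- cfg@nCols
  gl <- .geneLoadings(cfg)
  mask <- .ellipseMask(nR, nC)
  flat <- matrix(latentFields, nR * nC, cfg@nFactors)
  meanFlat <- flat %*% t(gl$loadings)
  meanFlat <- sweep(meanFlat, 2, gl$depth, "*")
  gene <- sprintf("gene%02d", seq_len(cfg@nGenes))
  obs <- withSeed(cfg@seed + 303L, {
    if (cfg@noiseModel == "poisson") {
      matrix(stats::rpois(length(meanFlat), meanFlat), nrow(meanFlat))
    } else {
      pmax(meanFlat + stats::rnorm(length(meanFlat),
                                   sd = cfg@noiseScale * meanFlat), 0)
    }
  })
  vals <- array(obs, dim = c(nR, nC, cfg@nGenes),
                dimnames = list(NULL, NULL, gene))
  hr <- HighResExpression(vals, mask,
                          SuperpixelGrid(nR, nC, superpixelUm = 8,
                                         pixelSizeUm = 0.5))
  meanArr <- array(meanFlat, dim = c(nR, nC, cfg@nGenes),
                   dimnames = list(NULL, NULL, gene))
  for (k in seq_len(cfg@nGenes)) meanArr[, , k][!mask] <- 0
  attr(hr, "meanField") <- meanArr
  attr(hr, "loadings") <- gl$loadings
  hr
}

# distinct base stain colours per factor (RGB absorption, H&E-like hues)
.factorColors <- function(nFactors) {
  base <- rbind(c(0.55, 0.15, 0.45),  # purple
                c(0.15, 0.50, 0.50),  # teal
                c(0.55, 0.45, 0.10),  # ochre
                c(0.10, 0.25, 0.60),  # blue
                c(0.50, 0.30, 0.30))  # brown
  base[(seq_len(nFactors) - 1L) %% nrow(base) + 1L, , drop = FALSE]
}

#' Render a pseudo-histology image from the latent fields
#'
#' Each factor absorbs a distinct colour; per-superpixel colour is white
#' minus the factor-weighted absorptions (with a light uniform tissue tint
#' inside the mask so unstained tissue is still detectable). The
#' superpixel colours are upsampled 16x to 0.5 um/px and seeded texture
#' noise of amplitude `textureAmplitude` is added. By construction,
#' patch-local image statistics are (affinely) informative of the latent
#' fields.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param latentFields array from [generateLatentFields()].
#' @return RGB array (nRows*16, nCols*16, 3) in [0, 1].
#' @export
generateHistology <- function(cfg, latentFields = generateLatentFields(cfg)) {
  nR <- cfg@nRows; nC <- cfg@nCols
  mask <- .ellipseMask(nR, nC)
  cols <- .factorColors(cfg@nFactors)
  img <- array(1, dim = c(nR, nC, 3))
  tint <- c(0.12, 0.28, 0.12)  # pink tissue background, distinct from slide
  for (ch in 1:3) {
    absorb <- matrix(0, nR, nC)
    for (f in seq_len(cfg@nFactors))
      absorb <- absorb + latentFields[, , f] * cols[f, ch] * 0.8
    plane <- 1 - tint[ch] - absorb
    plane[!mask] <- 1
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  up <- 16L
  big <- array(0, dim = c(nR * up, nC * up, 3))
  ridx <- rep(seq_len(nR), each = up)
  cidx <- rep(seq_len(nC), each = up)
  for (ch in 1:3) big[, , ch] <- img[ridx, cidx, ch]
  if (cfg@textureAmplitude > 0) {
    noise <- withSeed(cfg@seed + 404L,
      array(stats::runif(length(big), -cfg@textureAmplitude,
                         cfg@textureAmplitude), dim = dim(big)))
    big <- pmin(pmax(big + noise, 0), 1)
  }
  big
}

#' Sample a cell table consistent with the ground truth
#'
#' Seeded point process: cells sit at jittered centers of in-mask
#' superpixels (one per sampled superpixel at the configured density);
#' each cell's expression is its superpixel's ground-truth value scaled by
#' a lognormal size factor, with a square footprint of seeded area.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param groundTruth a [HighResExpression-class] from
#'   [generateGroundTruth()].
#' @param density cells per in-mask superpixel (default 1: one cell per
#'   single-cell-sized superpixel, the dense-tissue regime).
#' @return a [CellTable-class].
#' @export
generateCells <- function(cfg, groundTruth, density = 1) {
  grid <- superpixelGridOf(groundTruth)
  mask <- validMask(groundTruth)
  vals <- expressionField(groundTruth)
  s <- grid@superpixelUm
  inMask <- which(mask, arr.ind = TRUE)
  withSeed(cfg@seed + 505L, {
    n <- max(2L, round(nrow(inMask) * density))
    pick <- sample.int(nrow(inMask), n, replace = FALSE)
    rc <- inMask[pick, , drop = FALSE]
    jit <- matrix(stats::runif(2 * n, -0.3, 0.3), n, 2)
    cx <- grid@originUm[1] + (rc[, 2] - 0.5 + jit[, 1]) * s
    cy <- grid@originUm[2] + (rc[, 1] - 0.5 + jit[, 2]) * s
    sizeFactor <- exp(stats::rnorm(n, 0, 0.3))
    expr <- matrix(0, n, dim(vals)[3],
                   dimnames = list(NULL, dimnames(vals)[[3]]))
    for (i in seq_len(n)) expr[i, ] <- vals[rc[i, 1], rc[i, 2], ] * sizeFactor[i]
    areas <- stats::runif(n, 30, 80)
    CellTable(expr, cbind(cx, cy), areas)
  })
}

#' Assemble the full synthetic benchmark
#'
#' Composes ground truth, pseudo-histology image, a hexagonal pseudo-spot
#' layout (diameter 55, pitch 100 by default) restricted to spots covering
#' at least one in-mask superpixel, and the pseudo-Visium spot expression
#' aggregated from the truth by disc summation — everything needed for an
#' end-to-end train / infer / evaluate run with known ground truth.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param diameterUm,pitchUm spot geometry (defaults 55, 100).
#' @return list with `image`, `layout`, `spots`, `truth`, `latentFields`,
#'   `config`.
#' @export
makeBenchmark <- function(cfg = syntheticConfig(), diameterUm = 55,
                          pitchUm = 100) {
  latent <- generateLatentFields(cfg)
  truth <- generateGroundTruth(cfg, latent)
  image <- generateHistology(cfg, latent)
  grid <- superpixelGridOf(truth)
  bbox <- c(grid@originUm[1], grid@originUm[2],
            grid@originUm[1] + grid@nCols * grid@superpixelUm,
            grid@originUm[2] + grid@nRows * grid@superpixelUm)
  layout <- makeSpotLayout(bbox, diameterUm, pitchUm, "hex")
  # keep in-tissue spots: disc must cover >= 1 in-mask superpixel center
  sp <- superpixelCenters(grid)
  mask <- validMask(truth)
  r <- diameterUm / 2
  ctr <- spotCenters(layout)
  keep <- vapply(seq_len(nrow(ctr)), function(j) {
    sel <- outer((sp$y - ctr[j, 2])^2, (sp$x - ctr[j, 1])^2, "+") <= r^2
    any(sel & mask)
  }, logical(1))
  layout <- SpotLayout(ctr[keep, , drop = FALSE], diameterUm, pitchUm, "hex")
  spots <- pseudoVisiumFromBins(truth, layout)
  list(image = image, layout = layout, spots = spots, truth = truth,
       latentFields = latent, config = cfg)
}
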
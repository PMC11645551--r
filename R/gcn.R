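# The method core: per-spot lattice graphs, a two-layer graph
# convolutional network with a non-negative output head, the circular-
# filter weak-supervision loss, Adam training, and tiled whole-slide
# inference.
#
# Weak supervision: no superpixel-level labels exist. Each training unit is
# the D x D block of the multimodal feature map under one spot; the model
# predicts expression for all D^2 superpixels and the sum over superpixels
# whose centers fall inside the spot's circular capture area must match the
# observed spot expression. Training minimises the squared difference,
# summed over spots and genes, on the linear count scale.

#' Number of superpixels spanned by a spot diameter
#'
#' `D = round(diameterUm / superpixelUm)` with round-half-up, at least 1.
#' The default Visium geometry (55 um spots, 8 um superpixels) gives D = 7.
#'
#' @param diameterUm spot diameter.
#' @param superpixelUm superpixel side length.
#' @return integer patch span D.
#' @export
computePatchSpan <- function(diameterUm, superpixelUm) {
  max(1L, as.integer(floor(diameterUm / superpixelUm + 0.5)))
}

#' Build the shared D x D lattice graph
#'
#' Nodes are the D^2 superpixels of a patch in row-major order. Each node's
#' four closest neighbours by physical distance are its von Neumann lattice
#' neighbours (up, down, left, right); border nodes keep only the
#' neighbours that exist. Self-loops are added and the adjacency normalised
#' symmetrically (`D^-1/2 (A+I) D^-1/2`) by default; `normalize = "row"`
#' gives a row-stochastic operator and `"none"` the raw A + I.
#'
#' @param D patch side length in superpixels.
#' @param normalize "sym" (default), "row" or "none".
#' @return a [GridGraph-class].
#' @export
buildAdjacency <- function(D, normalize = c("sym", "row", "none")) {
  normalize <- match.arg(normalize)
  D <- as.integer(D)
  if (D < 1L) stop("D must be >= 1")
  n <- D * D
  idx <- function(r, c) (r - 1L) * D + c  # row-major node order
  from <- integer(0); to <- integer(0)
  if (D > 1L) {
    # horizontal edges
    r <- rep(seq_len(D), each = D - 1L)
    c <- rep(seq_len(D - 1L), times = D)
    from <- c(from, idx(r, c)); to <- c(to, idx(r, c + 1L))
    # vertical edges
    r <- rep(seq_len(D - 1L), times = D)
    c <- rep(seq_len(D), each = D - 1L)
    from <- c(from, idx(r, c)); to <- c(to, idx(r + 1L, c))
  }
  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                            x = 1, dims = c(n, n))
  A <- A + Matrix::Diagonal(n)
  if (normalize == "sym") {
    dhalf <- 1 / sqrt(Matrix::rowSums(A))
    A <- Matrix::Diagonal(n, dhalf) %*% A %*% Matrix::Diagonal(n, dhalf)
  } else if (normalize == "row") {
    A <- Matrix::Diagonal(n, 1 / Matrix::rowSums(A)) %*% A
  }
  new("GridGraph", adjacency = methods::as(A, "CsparseMatrix"),
      D = D, normalization = normalize)
}

# row-major flatten of a (D, D, C) block into a (D^2, C) node matrix
.flattenPatch <- function(features) {
  d <- dim(features)
  matrix(aperm(features, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

# inverse: (D^2, K) node matrix back to (D, D, K)
.unflattenPatch <- function(mat, D) {
  aperm(array(mat, dim = c(D, D, ncol(mat))), c(2, 1, 3))
}

#' Cut per-spot training patches out of the feature map
#'
#' For each spot the D x D block of superpixels centered on the superpixel
#' containing the spot center is extracted (block top-left = center
#' superpixel minus floor(D/2); out-of-map positions zero-padded). The
#' circular filter marks superpixels whose centers lie within the spot
#' radius of the spot center and inside the map; padded positions are
#' excluded from the filter but remain graph nodes. Spots whose center
#' falls off the map are skipped with a warning, as are spots whose filter
#' would be empty.
#'
#' @param featureMap a [MultimodalFeatureMap-class].
#' @param spotExpr a [SpotExpression-class]; rows are the weak labels.
#' @param D patch span (default from the layout and grid geometry).
#' @return list of [SpotPatch-class].
#' @export
buildSpotPatches <- function(featureMap, spotExpr,
                             D = computePatchSpan(spotDiameter(spotExpr),
                                                  superpixelGridOf(featureMap)@superpixelUm)) {
  grid <- superpixelGridOf(featureMap)
  ch <- featureChannels(featureMap)
  layout <- spotLayout(spotExpr)
  ctr <- spotCenters(layout)
  counts <- spotCounts(spotExpr)
  r <- spotDiameter(layout) / 2
  s <- grid@superpixelUm
  half <- D %/% 2L
  sp <- superpixelCenters(grid)
  C <- dim(ch)[3]
  patches <- vector("list", nrow(ctr))
  skipped <- 0L
  for (j in seq_len(nrow(ctr))) {
    m0 <- floor((ctr[j, 2] - grid@originUm[2]) / s) + 1L
    n0 <- floor((ctr[j, 1] - grid@originUm[1]) / s) + 1L
    if (m0 < 1L || m0 > grid@nRows || n0 < 1L || n0 > grid@nCols) {
      skipped <- skipped + 1L
      next
    }
    rows <- (m0 - half):(m0 - half + D - 1L)
    cols <- (n0 - half):(n0 - half + D - 1L)
    feat <- array(0, dim = c(D, D, C))
    inR <- which(rows >= 1L & rows <= grid@nRows)
    inC <- which(cols >= 1L & cols <= grid@nCols)
    feat[inR, inC, ] <- ch[rows[inR], cols[inC], , drop = FALSE]
    filt <- matrix(FALSE, D, D)
    cy <- sp$y[rows[inR]]; cx <- sp$x[cols[inC]]
    filt[inR, inC] <- outer((cy - ctr[j, 2])^2, (cx - ctr[j, 1])^2, "+") <= r^2
    if (!any(filt)) {
      skipped <- skipped + 1L
      next
    }
    patches[[j]] <- new("SpotPatch", features = feat, filter = filt,
                        label = counts[j, ], spotId = j)
  }
  if (skipped > 0L)
    warning(skipped, " spot(s) off the map or with empty filter; skipped")
  Filter(Negate(is.null), patches)
}

#' Initialise a super-resolution model
#'
#' Hidden weights use seeded Glorot-uniform initialisation; the output head
#' (weights and bias) starts at zero, so early training fits per-gene mean
#' rates through the bias before spatial structure enters via the hidden
#' layers, and identical label columns evolve identically.
#'
#' @param C input channels.
#' @param geneNames character vector naming the K output genes.
#' @param hiddenDim hidden width (default 512).
#' @param seed RNG seed for the hidden weights.
#' @return a [SuperResModel-class].
#' @export
newSuperResModel <- function(C, geneNames, hiddenDim = 512L, seed = 0) {
  h <- as.integer(hiddenDim)
  K <- length(geneNames)
  withSeed(seed, {
    lim0 <- sqrt(6 / (C + h)); lim1 <- sqrt(6 / (h + h))
    W0 <- matrix(stats::runif(C * h, -lim0, lim0), C, h)
    W1 <- matrix(stats::runif(h * h, -lim1, lim1), h, h)
    new("SuperResModel", W0 = W0, W1 = W1,
        W2 = matrix(0, h, K), b = numeric(K),
        hiddenDim = h, geneNames = as.character(geneNames),
        seed = as.integer(seed))
  })
}

#' Forward pass of the GCN on one patch
#'
#' `Z = eluPlusOne( ReLU(A ReLU(A X W0) W1) W2 + b )` with X the row-major
#' flatten of the D x D x C block and A the (normalised) patch adjacency.
#' `eluPlusOne(x) = elu(x) + 1` keeps every predicted expression strictly
#' positive. Row order of the output matches the flatten order.
#'
#' @param model a [SuperResModel-class].
#' @param patchFeatures D x D x C array (or an already flattened D^2 x C
#'   matrix).
#' @param graph the [GridGraph-class] for this D.
#' @param returnHidden also return hidden activations.
#' @return D^2 x K non-negative matrix; with `returnHidden = TRUE`, a list
#'   with `Z`, `H1`, `H2`.
#' @export
gcnForward <- function(model, patchFeatures, graph, returnHidden = FALSE) {
  X <- if (is.matrix(patchFeatures)) patchFeatures
       else .flattenPatch(patchFeatures)
  if (ncol(X) != nrow(model@W0))
    stop(sprintf("feature channels (%d) do not match model input dim (%d)",
                 ncol(X), nrow(model@W0)))
  A <- graph@adjacency
  if (nrow(X) != nrow(A))
    stop(sprintf("patch has %d nodes but graph has %d", nrow(X), nrow(A)))
  H1 <- pmax(as.matrix(A %*% X) %*% model@W0, 0)
  H2 <- pmax(as.matrix(A %*% H1) %*% model@W1, 0)
  pre <- sweep(H2 %*% model@W2, 2, model@b, "+")
  Z <- .eluPlusOne(pre)
  colnames(Z) <- model@geneNames
  if (returnHidden) list(Z = Z, H1 = H1, H2 = H2) else Z
}

#' Circular-filter weak-supervision loss
#'
#' The spot-level prediction is the column sum of the predicted node
#' expression over filtered (in-disc) nodes; the loss is the squared L2
#' distance to the observed label, summed over genes — and over spots when
#' given lists.
#'
#' @param pred D^2 x K prediction (or list of them).
#' @param filter D x D logical filter (or list), row-major order matching
#'   `pred` rows.
#' @param label length-K observed expression (or list/matrix of labels).
#' @return scalar loss.
#' @export
weakSupervisionLoss <- function(pred, filter, label) {
  one <- function(p, f, l) {
    fv <- as.vector(t(f))  # row-major node order
    if (!any(fv)) {
      warning("empty filter; spot excluded from the loss")
      return(0)
    }
    m <- colSums(p[fv, , drop = FALSE])
    sum((l - m)^2)
  }
  if (is.list(pred)) {
    lab <- if (is.matrix(label)) lapply(seq_len(nrow(label)), function(i) label[i, ])
           else label
    sum(mapply(function(p, f, l) one(p, f, l), pred, filter, lab))
  } else one(pred, filter, label)
}

# --- internal batched forward/backward over a shared block-diagonal graph ---

# builds per-batch-size cache of bdiag(A, ..., A)
.bigA <- function(A, B, cache) {
  key <- as.character(B)
  if (is.null(cache[[key]]))
    cache[[key]] <- methods::as(Matrix::bdiag(rep(list(A), B)), "CsparseMatrix")
  cache[[key]]
}

.forwardBatch <- function(W0, W1, W2, b, Xbig, Abig) {
  AX <- as.matrix(Abig %*% Xbig)
  pre1 <- AX %*% W0
  H1 <- pmax(pre1, 0)
  AH1 <- as.matrix(Abig %*% H1)
  pre2 <- AH1 %*% W1
  H2 <- pmax(pre2, 0)
  preZ <- sweep(H2 %*% W2, 2, b, "+")
  Z <- .eluPlusOne(preZ)
  list(AX = AX, pre1 = pre1, H1 = H1, AH1 = AH1, pre2 = pre2, H2 = H2,
       preZ = preZ, Z = Z)
}

.backwardBatch <- function(fw, W1, W2, dZ, Abig) {
  dpreZ <- dZ * .eluPlusOnePrime(fw$preZ, fw$Z)
  dW2 <- crossprod(fw$H2, dpreZ)
  db <- colSums(dpreZ)
  dH2 <- dpreZ %*% t(W2)
  dpre2 <- dH2 * (fw$pre2 > 0)
  dW1 <- crossprod(fw$AH1, dpre2)
  dH1 <- as.matrix(Abig %*% (dpre2 %*% t(W1)))  # A symmetric
  dpre1 <- dH1 * (fw$pre1 > 0)
  dW0 <- crossprod(fw$AX, dpre1)
  list(dW0 = dW0, dW1 = dW1, dW2 = dW2, db = db)
}

#' Training configuration
#'
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize spots per gradient step (default 32).
#' @param epochs maximum epochs (default 300).
#' @param seed RNG seed for init and shuffling (default 0).
#' @param patience epochs without training-loss improvement before early
#'   stop (default 50).
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 1e-3, batchSize = 32L, epochs = 300L,
                        seed = 0L, patience = 50L) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), patience = as.integer(patience))
}

#' Train the GCN under weak supervision
#'
#' Minimises the circular-filter loss with Adam over mini-batches of spots.
#' Fully deterministic given the config seed: hidden weights, batch
#' shuffling and everything downstream are driven by it. The output bias is
#' initialised to the inverse output activation of the mean label per
#' filtered superpixel, so optimisation starts at the per-gene mean rate.
#' Training aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param patches list of [SpotPatch-class] from [buildSpotPatches()].
#' @param graph the shared [GridGraph-class].
#' @param config a [TrainConfig-class].
#' @param hiddenDim hidden width (default 512).
#' @param verbose print the loss every 25 epochs.
#' @return list with `model` ([SuperResModel-class]) and `lossHistory`
#'   (numeric, one summed training loss per epoch).
#' @export
trainSuperRes <- function(patches, graph, config = trainConfig(),
                          hiddenDim = 512L, verbose = FALSE) {
  if (length(patches) < 2L) stop("need at least 2 spots to train")
  C <- dim(patches[[1]]@features)[3]
  K <- length(patches[[1]]@label)
  gn <- names(patches[[1]]@label)
  if (is.null(gn)) gn <- paste0("gene", seq_len(K))
  S <- length(patches)
  N <- graph@D^2
  X <- lapply(patches, function(p) .flattenPatch(p@features))
  filt <- matrix(vapply(patches, function(p) as.vector(t(p@filter)),
                        logical(N)), nrow = N)
  labels <- do.call(rbind, lapply(patches, function(p) p@label))
  nFilt <- colSums(filt)

  withSeed(config@seed, {
    model <- newSuperResModel(C, gn, hiddenDim, seed = config@seed)
    # start at the per-gene mean rate per in-disc superpixel
    rate <- colMeans(labels / nFilt)
    b <- .eluPlusOneInv(rate)
    W0 <- model@W0; W1 <- model@W1; W2 <- model@W2
    adam <- list(m = lapply(list(W0, W1, W2, b), function(x) x * 0),
                 v = lapply(list(W0, W1, W2, b), function(x) x * 0),
                 t = 0L)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; lr <- config@learningRate
    Acache <- new.env(parent = emptyenv())
    A1 <- graph@adjacency
    lossHistory <- numeric(0)
    best <- Inf; bestEpoch <- 0L
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(S)
      epochLoss <- 0
      for (start in seq(1L, S, by = config@batchSize)) {
        ids <- ord[start:min(start + config@batchSize - 1L, S)]
        B <- length(ids)
        Abig <- .bigA(A1, B, Acache)
        Xbig <- do.call(rbind, X[ids])
        fw <- .forwardBatch(W0, W1, W2, b, Xbig, Abig)
        # spot-level sums via the filter, per batch member
        fsel <- as.vector(filt[, ids])
        grp <- rep(seq_len(B), each = N)[fsel]
        M <- rowsum(fw$Z[fsel, , drop = FALSE], grp)
        resid <- M - labels[ids, , drop = FALSE]
        epochLoss <- epochLoss + sum(resid^2)
        dZ <- matrix(0, B * N, K)
        dZ[fsel, ] <- 2 * resid[grp, , drop = FALSE]
        gr <- .backwardBatch(fw, W1, W2, dZ, Abig)
        adam$t <- adam$t + 1L
        gl <- list(gr$dW0, gr$dW1, gr$dW2, gr$db)
        for (p in 1:4) {
          adam$m[[p]] <- beta1 * adam$m[[p]] + (1 - beta1) * gl[[p]]
          adam$v[[p]] <- beta2 * adam$v[[p]] + (1 - beta2) * gl[[p]]^2
          mhat <- adam$m[[p]] / (1 - beta1^adam$t)
          vhat <- adam$v[[p]] / (1 - beta2^adam$t)
          step <- lr * mhat / (sqrt(vhat) + eps)
          if (p == 1L) W0 <- W0 - step
          else if (p == 2L) W1 <- W1 - step
          else if (p == 3L) W2 <- W2 - step
          else b <- b - step
        }
      }
      if (!is.finite(epochLoss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (reduce learningRate)")
      lossHistory <- c(lossHistory, epochLoss)
      if (verbose && epoch %% 25L == 0L)
        message(sprintf("epoch %d: loss %.4g", epoch, epochLoss))
      if (epochLoss < best * (1 - 1e-6)) {
        best <- epochLoss; bestEpoch <- epoch
      } else if (epoch - bestEpoch >= config@patience) break
    }
    model@W0 <- W0; model@W1 <- W1; model@W2 <- W2; model@b <- b
    list(model = model, lossHistory = lossHistory)
  })
}

# pad the channel array to multiples of D and enumerate D x D tiles
.tileMap <- function(ch, D) {
  d <- dim(ch)
  padR <- (D - d[1] %% D) %% D
  padC <- (D - d[2] %% D) %% D
  if (padR || padC) {
    out <- array(0, dim = c(d[1] + padR, d[2] + padC, d[3]))
    out[seq_len(d[1]), seq_len(d[2]), ] <- ch
    ch <- out
  }
  list(ch = ch, nTR = dim(ch)[1] %/% D, nTC = dim(ch)[2] %/% D,
       padR = padR, padC = padC)
}

# run the model over every tile of the map; fn picks which output to keep
.predictTiles <- function(model, graph, ch, D, outDim, pick) {
  tm <- .tileMap(ch, D)
  N <- D * D
  nTiles <- tm$nTR * tm$nTC
  Xs <- vector("list", nTiles)
  t <- 0L
  for (i in seq_len(tm$nTR)) for (j in seq_len(tm$nTC)) {
    t <- t + 1L
    Xs[[t]] <- .flattenPatch(tm$ch[((i - 1) * D + 1):(i * D),
                                   ((j - 1) * D + 1):(j * D), , drop = FALSE])
  }
  out <- array(0, dim = c(tm$nTR * D, tm$nTC * D, outDim))
  # batch tiles through the shared graph in chunks
  chunk <- max(1L, 2048L %/% N)
  Acache <- new.env(parent = emptyenv())
  for (start in seq(1L, nTiles, by = chunk)) {
    ids <- start:min(start + chunk - 1L, nTiles)
    Abig <- .bigA(graph@adjacency, length(ids), Acache)
    fw <- .forwardBatch(model@W0, model@W1, model@W2, model@b,
                        do.call(rbind, Xs[ids]), Abig)
    vals <- pick(fw)
    for (q in seq_along(ids)) {
      t <- ids[q] - 1L
      i <- t %/% tm$nTC + 1L; j <- t %% tm$nTC + 1L
      blk <- .unflattenPatch(vals[((q - 1) * N + 1):(q * N), , drop = FALSE], D)
      out[((i - 1) * D + 1):(i * D), ((j - 1) * D + 1):(j * D), ] <- blk
    }
  }
  out[seq_len(dim(ch)[1]), seq_len(dim(ch)[2]), , drop = FALSE]
}

#' Infer super-resolution expression over the whole slide
#'
#' The multimodal map is zero-padded to multiples of D, divided into
#' non-overlapping D x D tiles, each tile predicted with the shared graph
#' and trained model, the blocks reassembled in place, the padding cropped,
#' and superpixels outside the tissue mask set to zero.
#'
#' @param featureMap a [MultimodalFeatureMap-class].
#' @param model a trained [SuperResModel-class].
#' @param graph the [GridGraph-class] used in training.
#' @param mask logical tissue mask (rows x cols).
#' @return a [HighResExpression-class].
#' @export
inferSuperRes <- function(featureMap, model, graph, mask) {
  ch <- featureChannels(featureMap)
  if (dim(ch)[3] != nrow(model@W0))
    stop(sprintf("map has %d channels but model expects %d",
                 dim(ch)[3], nrow(model@W0)))
  vals <- .predictTiles(model, graph, ch, graph@D, ncol(model@W2),
                        function(fw) fw$Z)
  HighResExpression(vals, mask, superpixelGridOf(featureMap),
                    geneNames = model@geneNames)
}

#' Export per-superpixel GCN features
#'
#' Second-layer GCN activations (the 512-dimensional per-superpixel
#' representation), assembled over the slide exactly like
#' [inferSuperRes()] and zeroed outside the mask. These are the features
#' used for k-means tissue segmentation.
#'
#' @inheritParams inferSuperRes
#' @return numeric array (rows, cols, hiddenDim).
#' @export
exportGcnFeatures <- function(featureMap, model, graph, mask) {
  ch <- featureChannels(featureMap)
  if (dim(ch)[3] != nrow(model@W0))
    stop(sprintf("map has %d channels but model expects %d",
                 dim(ch)[3], nrow(model@W0)))
  out <- .predictTiles(model, graph, ch, graph@D, model@hiddenDim,
                       function(fw) fw$H2)
  for (k in seq_len(dim(out)[3])) out[, , k][!mask] <- 0
  out
}
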
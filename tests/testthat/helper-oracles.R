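# Independent brute-force oracles. These deliberately share no code with
# the package implementation: plain double loops and dense arithmetic.

# enumerate a centered square/hex lattice inside a bbox, keeping a margin r
oracleLattice <- function(bbox, pitch, r, lattice) {
  xmin <- bbox[1] + r; xmax <- bbox[3] - r
  ymin <- bbox[2] + r; ymax <- bbox[4] - r
  pts <- NULL
  if (lattice == "square") {
    nx <- floor((xmax - xmin) / pitch + 1e-9) + 1
    ny <- floor((ymax - ymin) / pitch + 1e-9) + 1
    x0 <- xmin + (xmax - xmin - (nx - 1) * pitch) / 2
    y0 <- ymin + (ymax - ymin - (ny - 1) * pitch) / 2
    for (iy in 0:(ny - 1)) for (ix in 0:(nx - 1))
      pts <- rbind(pts, c(x0 + ix * pitch, y0 + iy * pitch))
  } else {
    dy <- pitch * sqrt(3) / 2
    ny <- floor((ymax - ymin) / dy + 1e-9) + 1
    y0 <- ymin + (ymax - ymin - (ny - 1) * dy) / 2
    nx <- floor((xmax - xmin) / pitch + 1e-9) + 1
    x0 <- xmin + (xmax - xmin - (nx - 1) * pitch) / 2
    for (iy in 0:(ny - 1)) {
      off <- if (iy %% 2 == 1) pitch / 2 else 0
      for (ix in 0:(nx - 1)) {
        x <- x0 + ix * pitch + off
        if (x >= xmin - 1e-9 && x <= xmax + 1e-9)
          pts <- rbind(pts, c(x, y0 + iy * dy))
      }
    }
  }
  pts
}

# double loop: sum field vectors over superpixel centers within r of spots
oracleBinsToSpots <- function(vals, grid, centers, r) {
  nR <- dim(vals)[1]; nC <- dim(vals)[2]; K <- dim(vals)[3]
  s <- grid@superpixelUm
  out <- matrix(0, nrow(centers), K)
  for (j in seq_len(nrow(centers))) {
    for (m in seq_len(nR)) for (n in seq_len(nC)) {
      cy <- grid@originUm[2] + (m - 0.5) * s
      cx <- grid@originUm[1] + (n - 0.5) * s
      if ((cx - centers[j, 1])^2 + (cy - centers[j, 2])^2 <= r^2)
        out[j, ] <- out[j, ] + vals[m, n, ]
    }
  }
  out
}

# double loop: nearest-spot centroid membership
oracleCellsToSpots <- function(expr, cen, centers, r) {
  out <- matrix(0, nrow(centers), ncol(expr))
  for (k in seq_len(nrow(cen))) {
    d <- sqrt((centers[, 1] - cen[k, 1])^2 + (centers[, 2] - cen[k, 2])^2)
    j <- which.min(d)
    if (d[j] <= r) out[j, ] <- out[j, ] + expr[k, ]
  }
  out
}

# double loop: box footprint / grid cell overlap partition
oracleCellsToGrid <- function(expr, boxes, areas, grid) {
  nR <- grid@nRows; nC <- grid@nCols; s <- grid@superpixelUm
  out <- array(0, dim = c(nR, nC, ncol(expr)))
  for (k in seq_len(nrow(boxes))) {
    for (m in seq_len(nR)) for (n in seq_len(nC)) {
      gx1 <- grid@originUm[1] + (n - 1) * s; gx2 <- gx1 + s
      gy1 <- grid@originUm[2] + (m - 1) * s; gy2 <- gy1 + s
      ox <- max(0, min(boxes[k, 3], gx2) - max(boxes[k, 1], gx1))
      oy <- max(0, min(boxes[k, 4], gy2) - max(boxes[k, 2], gy1))
      if (ox > 0 && oy > 0)
        out[m, n, ] <- out[m, n, ] + (ox * oy / areas[k]) * expr[k, ]
    }
  }
  out
}

# dense lattice adjacency from the edge rule, with optional normalisation
oracleAdjacencyDense <- function(D, normalize = "sym") {
  n <- D * D
  A <- matrix(0, n, n)
  for (r1 in 1:D) for (c1 in 1:D) for (r2 in 1:D) for (c2 in 1:D) {
    if (abs(r1 - r2) + abs(c1 - c2) == 1)
      A[(r1 - 1) * D + c1, (r2 - 1) * D + c2] <- 1
  }
  A <- A + diag(n)
  if (normalize == "sym") {
    d <- rowSums(A)
    A <- diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  } else if (normalize == "row") {
    A <- diag(1 / rowSums(A)) %*% A
  }
  A
}

# dense forward chain with naive loops for the activations
oracleForwardDense <- function(W0, W1, W2, b, X, Adense) {
  relu <- function(m) { m[m < 0] <- 0; m }
  elup1 <- function(m) { out <- m; out[m > 0] <- m[m > 0] + 1
                         out[m <= 0] <- exp(m[m <= 0]); out }
  H1 <- relu(Adense %*% X %*% W0)
  H2 <- relu(Adense %*% H1 %*% W1)
  pre <- H2 %*% W2
  for (i in seq_len(nrow(pre))) pre[i, ] <- pre[i, ] + b
  elup1(pre)
}

# per-spot loop loss
oracleLoss <- function(preds, filters, labels) {
  total <- 0
  for (j in seq_along(preds)) {
    fv <- as.vector(t(filters[[j]]))
    m <- rep(0, ncol(preds[[j]]))
    for (i in which(fv)) m <- m + preds[[j]][i, ]
    total <- total + sum((labels[[j]] - m)^2)
  }
  total
}

# sliding-window SSIM with reflection padding, per-center loop
oracleSSIM <- function(a, b, mask, win = 11, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03) {
  h <- (win - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  C1 <- K1^2; C2 <- K2^2
  nR <- nrow(a); nC <- ncol(a)
  vals <- c()
  for (i in seq_len(nR)) for (j in seq_len(nC)) {
    if (!mask[i, j]) next
    ri <- reflect(i + (-h:h), nR); cj <- reflect(j + (-h:h), nC)
    pa <- a[ri, cj]; pb <- b[ri, cj]
    m1 <- sum(w * pa); m2 <- sum(w * pb)
    v1 <- sum(w * pa^2) - m1^2; v2 <- sum(w * pb^2) - m2^2
    cv <- sum(w * pa * pb) - m1 * m2
    vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * cv + C2)) /
                ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
  }
  mean(vals)
}

# 16 x 16 block means by loops
oracleBlockMean <- function(img, p = 16) {
  nR <- dim(img)[1] / p; nC <- dim(img)[2] / p
  out <- array(0, dim = c(nR, nC, dim(img)[3]))
  for (i in seq_len(nR)) for (j in seq_len(nC)) for (ch in seq_len(dim(img)[3]))
    out[i, j, ch] <- mean(img[((i - 1) * p + 1):(i * p),
                              ((j - 1) * p + 1):(j * p), ch])
  out
}

# a small random cell table fully inside [0, extent]^2
randomCellTable <- function(nCells, nGenes, extentUm, seed,
                            margin = 5) {
  withSeed(seed, {
    cen <- cbind(runif(nCells, margin, extentUm - margin),
                 runif(nCells, margin, extentUm - margin))
    areas <- runif(nCells, 10, 60)
    expr <- matrix(rpois(nCells * nGenes, 5), nCells, nGenes,
                   dimnames = list(NULL, sprintf("g%02d", seq_len(nGenes))))
    CellTable(expr, cen, areas)
  })
}
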
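# Small internal helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded components never perturb user randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# elu(x) + 1: smooth strictly positive output activation
.eluPlusOne <- function(x) ifelse(x > 0, x + 1, exp(x))

# derivative of elu(x) + 1 expressed through its value z = eluPlusOne(x)
.eluPlusOnePrime <- function(x, z) ifelse(x > 0, 1, z)

# inverse of elu(x) + 1 on (0, Inf)
.eluPlusOneInv <- function(y) {
  y <- pmax(y, 1e-6)
  ifelse(y >= 1, y - 1, log(y))
}

# 2-D convolution with reflection padding, 'same' output size
.conv2Reflect <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  xp <- x[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) for (b in seq_len(kc)) {
    out <- out + kernel[a, b] *
      xp[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

# normalized 2-D Gaussian kernel
.gaussianKernel <- function(size = 11L, sigma = 1.5) {
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}
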
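## Internal helpers: scoped RNG, separable convolution, pyramid primitives.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards, so seeded operations never disturb the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## 5-tap binomial kernel used throughout the pyramid.
.pyrKernel <- c(1, 4, 6, 4, 1) / 16

## Convolve the rows of a matrix with a short symmetric kernel,
## replicating edges. `m` is H x K; the kernel runs along dim 1.
.convRows <- function(m, kernel) {
  h <- nrow(m)
  half <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow = h, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    d <- j - 1L - half
    idx <- pmin.int(pmax.int(seq_len(h) + d, 1L), h)
    out <- out + kernel[j] * m[idx, , drop = FALSE]
  }
  out
}

## As .convRows but without edge replication (out-of-range taps read zero);
## used for the normalized expansion step.
.convRowsZero <- function(m, kernel) {
  h <- nrow(m)
  half <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow = h, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    d <- j - 1L - half
    src <- seq_len(h) + d
    ok <- src >= 1L & src <= h
    out[ok, ] <- out[ok, , drop = FALSE] +
      kernel[j] * m[src[ok], , drop = FALSE]
  }
  out
}

## Coerce a matrix to a 1-frame stack.
.asStack <- function(a) {
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  a
}

## Separable 2D blur of every frame in a stack (H x W x T), replicate edges.
.blurStack <- function(a, kernel = .pyrKernel) {
  a <- .asStack(a)
  d <- dim(a)
  m <- a
  dim(m) <- c(d[1], d[2] * d[3])
  m <- .convRows(m, kernel)
  dim(m) <- d
  m <- aperm(m, c(2, 1, 3))
  dim(m) <- c(d[2], d[1] * d[3])
  m <- .convRows(m, kernel)
  dim(m) <- c(d[2], d[1], d[3])
  aperm(m, c(2, 1, 3))
}

## Decimate a stack by 2 in both spatial dimensions (keep odd indices).
.downsampleStack <- function(a) {
  a <- .asStack(a)
  d <- dim(a)
  a[seq.int(1L, d[1], 2L), seq.int(1L, d[2], 2L), , drop = FALSE]
}

## 1D normalization profile for the expansion step: the zero-padded blur of
## the comb of sample positions, so that expanding a constant gives the same
## constant everywhere including the borders.
.expandNorm <- function(target, kernel) {
  comb <- matrix(0, nrow = target, ncol = 1L)
  comb[seq.int(1L, target, 2L), 1L] <- 1
  .convRowsZero(comb, 2 * kernel)[, 1L]
}

## Expand a stack to (targetH, targetW) by zero-insertion + normalized blur.
.expandStack <- function(a, targetH, targetW, kernel = .pyrKernel) {
  a <- .asStack(a)
  d <- dim(a)
  stopifnot(d[1] == ceiling(targetH / 2), d[2] == ceiling(targetW / 2))
  z <- array(0, dim = c(targetH, targetW, d[3]))
  z[seq.int(1L, targetH, 2L), seq.int(1L, targetW, 2L), ] <- a

  m <- z
  dim(m) <- c(targetH, targetW * d[3])
  m <- .convRowsZero(m, 2 * kernel) / .expandNorm(targetH, kernel)
  dim(m) <- c(targetH, targetW, d[3])
  m <- aperm(m, c(2, 1, 3))
  dim(m) <- c(targetW, targetH * d[3])
  m <- .convRowsZero(m, 2 * kernel) / .expandNorm(targetW, kernel)
  dim(m) <- c(targetW, targetH, d[3])
  aperm(m, c(2, 1, 3))
}

## Root-mean-square of a numeric vector.
.rms <- function(x) sqrt(mean(x^2))

## Clamp to [0, 1], returning the clamped array and the fraction clamped.
.clamp01 <- function(a) {
  sat <- mean(a < 0 | a > 1)
  a[a < 0] <- 0
  a[a > 1] <- 1
  list(a = a, saturation = sat)
}
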
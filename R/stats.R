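## Intra-run stability (split-half Bland-Altman) and idle-vs-scan inference
## (block bootstrap CI and block permutation test on RMS differences).

.seriesValues <- function(x) {
  if (is(x, "DisplacementSeries")) x@values else as.numeric(x)
}

#' Split a displacement series into half-clip RMS values
#'
#' Splits the series at its midpoint (an odd-length series gives the extra
#' frame to the first half), re-centers each half on its own mean, and
#' returns the RMS of each half. This is the intra-run stability measurand:
#' on a stationary vibration the two halves should agree.
#'
#' @param series A [DisplacementSeries] or numeric vector (length >= 4).
#' @return Data frame with one row: `rmsFirst`, `rmsSecond` (micrometres)
#'   plus `markerId`, `axis`, `condition` when the input is a
#'   [DisplacementSeries].
#' @examples
#' splitHalfPairs(c(1, -1, 1, -1))
#' @export
splitHalfPairs <- function(series) {
  v <- .seriesValues(series)
  n <- length(v)
  if (n < 4L)
    stop("need at least 4 samples to split into halves")
  nFirst <- ceiling(n / 2)
  a <- v[seq_len(nFirst)]
  b <- v[(nFirst + 1L):n]
  out <- data.frame(rmsFirst = .rms(a - mean(a)),
                    rmsSecond = .rms(b - mean(b)))
  if (is(series, "DisplacementSeries")) {
    out$markerId <- series@markerId
    out$axis <- series@axisLabel
    out$condition <- series@conditionLabel
  }
  out
}

#' Bland-Altman agreement between paired measurements
#'
#' For each pair, the difference is taken first minus second; with
#' `percent = TRUE` (default) it is expressed relative to the pair mean,
#' `d_i = 100 (a_i - b_i) / ((a_i + b_i) / 2)`. Reports the mean difference
#' and the 95% limits of agreement `mean(d) +/- 1.96 sd(d)` (sample SD).
#'
#' @param pairs Data frame with columns `rmsFirst` and `rmsSecond` (as
#'   returned by [splitHalfPairs()]), or a numeric vector of first-half
#'   values with `second` supplying the partner values.
#' @param second Optional numeric vector of second measurements.
#' @param percent Express differences in percent of the pair mean
#'   (default `TRUE`).
#' @return List with `meanDiff`, `loaLow`, `loaHigh`, `sd`, `n`. Limits of
#'   agreement are `NA` for a single pair.
#' @examples
#' blandAltman(c(1, 2, 1.1), c(1, 2, 0.9))
#' @export
blandAltman <- function(pairs, second = NULL, percent = TRUE) {
  if (is.data.frame(pairs)) {
    a <- pairs$rmsFirst
    b <- pairs$rmsSecond
  } else {
    a <- as.numeric(pairs)
    b <- as.numeric(second)
  }
  if (length(a) != length(b) || length(a) < 1L)
    stop("need at least one complete pair")
  d <- a - b
  if (percent) {
    m <- (a + b) / 2
    if (any(m == 0))
      stop("a pair with zero mean cannot be expressed in percent")
    d <- 100 * d / m
  }
  n <- length(d)
  md <- mean(d)
  s <- if (n > 1L) stats::sd(d) else NA_real_
  list(meanDiff = md,
       loaLow = if (n > 1L) md - 1.96 * s else NA_real_,
       loaHigh = if (n > 1L) md + 1.96 * s else NA_real_,
       sd = s, n = n)
}

## Moving-block resample of a series: k blocks of length L with uniformly
## random starts, concatenated and truncated to the original length.
.blockResample <- function(v, blockLen) {
  n <- length(v)
  k <- ceiling(n / blockLen)
  starts <- sample.int(n - blockLen + 1L, k, replace = TRUE)
  idx <- rep(starts, each = blockLen) + rep.int(seq_len(blockLen) - 1L, k)
  v[idx[seq_len(n)]]
}

.checkBlocks <- function(v, blockLen, what) {
  if (length(v) < 4L * blockLen)
    stop(sprintf("%s must cover at least 4 blocks of %d frames",
                 what, blockLen))
}

#' Block-bootstrap confidence interval for an RMS difference
#'
#' Point estimate is `rms(a) - rms(b)` on the re-centered series. Each
#' bootstrap replicate resamples whole contiguous blocks (moving-block
#' bootstrap) with replacement within each series independently, re-centers,
#' and recomputes the statistic; the 2.5 and 97.5 percentiles of the
#' replicates form the 95% CI. Blocks respect the strong autocorrelation of
#' displacement series. Fully reproducible from the seed in `spec`.
#'
#' @param seriesA,seriesB [DisplacementSeries] or numeric vectors, each at
#'   least 4 blocks long.
#' @param spec A [ResamplingSpec].
#' @return List with `rmsDiff`, `ciLo`, `ciHi` (micrometres), `nBoot`,
#'   `blockLenFrames`, `seed`.
#' @export
blockBootstrapCi <- function(seriesA, seriesB, spec = ResamplingSpec()) {
  stopifnot(is(spec, "ResamplingSpec"))
  a <- .seriesValues(seriesA)
  b <- .seriesValues(seriesB)
  L <- spec@blockLenFrames
  .checkBlocks(a, L, "'seriesA'")
  .checkBlocks(b, L, "'seriesB'")
  a <- a - mean(a)
  b <- b - mean(b)
  obs <- .rms(a) - .rms(b)
  reps <- withSeed(spec@seed, {
    vapply(seq_len(spec@nBoot), function(i) {
      ra <- .blockResample(a, L)
      rb <- .blockResample(b, L)
      .rms(ra - mean(ra)) - .rms(rb - mean(rb))
    }, numeric(1))
  })
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  list(rmsDiff = obs, ciLo = ci[1L], ciHi = ci[2L],
       nBoot = spec@nBoot, blockLenFrames = L, seed = spec@seed)
}

#' Block permutation test for an RMS difference
#'
#' Both series are cut into fixed contiguous blocks; condition labels are
#' permuted over the pooled blocks (preserving the per-condition block
#' counts), the series are reassembled and re-centered, and the statistic
#' `|rms(a*) - rms(b*)|` is recomputed. The two-sided p-value is
#' `(1 + #\{permuted >= observed\}) / (nPerm + 1)`, bounded below by
#' `1 / (nPerm + 1)`. Fully reproducible from the seed in `spec`.
#'
#' @param seriesA,seriesB [DisplacementSeries] or numeric vectors, each at
#'   least 4 blocks long.
#' @param spec A [ResamplingSpec].
#' @return List with `pTwoSided`, `observed`, `nPerm`, `blockLenFrames`,
#'   `seed`.
#' @export
permutationTestRms <- function(seriesA, seriesB, spec = ResamplingSpec()) {
  stopifnot(is(spec, "ResamplingSpec"))
  a <- .seriesValues(seriesA)
  b <- .seriesValues(seriesB)
  L <- spec@blockLenFrames
  .checkBlocks(a, L, "'seriesA'")
  .checkBlocks(b, L, "'seriesB'")
  a <- a - mean(a)
  b <- b - mean(b)
  obs <- abs(.rms(a) - .rms(b))
  blocksA <- split(a, ceiling(seq_along(a) / L))
  blocksB <- split(b, ceiling(seq_along(b) / L))
  pool <- c(blocksA, blocksB)
  nA <- length(blocksA)
  nTot <- length(pool)
  stats <- withSeed(spec@seed, {
    vapply(seq_len(spec@nPerm), function(i) {
      perm <- sample.int(nTot)
      pa <- unlist(pool[perm[seq_len(nA)]], use.names = FALSE)
      pb <- unlist(pool[perm[(nA + 1L):nTot]], use.names = FALSE)
      abs(.rms(pa - mean(pa)) - .rms(pb - mean(pb)))
    }, numeric(1))
  })
  p <- (1 + sum(stats >= obs)) / (spec@nPerm + 1)
  list(pTwoSided = p, observed = obs, nPerm = spec@nPerm,
       blockLenFrames = L, seed = spec@seed)
}
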
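## Eulerian video magnification: ideal temporal bandpass over the whole clip,
## applied per level of a Laplacian pyramid (or to a single lowpassed band),
## with the amplified band added back to the original.

## DFT-bin passband mask for n samples at rate fps: TRUE where the bin
## frequency |f| lies in [fLo, fHi] (DC always excluded since fLo > 0).
.bandMask <- function(n, band, fps) {
  f <- (seq_len(n) - 1L) * fps / n
  f <- pmin(f, fps - f)
  f >= band@fLo & f <= band@fHi
}

.checkBand <- function(band, fps) {
  stopifnot(is(band, "BandSpec"))
  if (band@fHi > fps / 2)
    stop(sprintf("passband edge %g Hz exceeds the Nyquist rate %g Hz",
                 band@fHi, fps / 2))
  invisible(band)
}

#' Ideal temporal bandpass filter
#'
#' Frequency-domain mask filter over the time axis: DFT coefficients whose
#' bin frequency lies in `[fLo, fHi]` are preserved and all others
#' (including DC) are zeroed, then the inverse transform is returned. The
#' output is therefore zero-mean, and exact for tones landing on DFT bins.
#'
#' @param series Numeric vector of length `T`, or a `T x P` matrix of `P`
#'   per-location series in its columns (time runs down the rows).
#' @param band A [BandSpec]; must satisfy `fHi <= fps / 2`.
#' @param fps Sampling rate in Hz.
#' @return Filtered series with the same shape as the input.
#' @examples
#' t <- (0:199) / 200
#' s <- 0.5 + 0.001 * sin(2 * pi * 30 * t)
#' f <- temporalIdealBandpass(s, BandSpec(10, 90), 200)
#' max(abs(f - 0.001 * sin(2 * pi * 30 * t)))
#' @export
temporalIdealBandpass <- function(series, band, fps) {
  .checkBand(band, fps)
  isVec <- is.null(dim(series))
  x <- if (isVec) matrix(series, ncol = 1L) else series
  n <- nrow(x)
  if (n < 4L)
    stop("need at least 4 time samples")
  keep <- .bandMask(n, band, fps)
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  y <- Re(stats::mvfft(X, inverse = TRUE)) / n
  if (isVec) y[, 1L] else y
}

## Bandpass a stack (H x W x T) along time, chunked over pixels to bound
## the size of the complex work arrays.
.bandpassStack <- function(a, band, fps, chunk = 8192L) {
  d <- dim(a)
  nPix <- d[1] * d[2]
  nT <- d[3]
  keep <- .bandMask(nT, band, fps)
  dim(a) <- c(nPix, nT)
  out <- matrix(0, nPix, nT)
  for (lo in seq.int(1L, nPix, chunk)) {
    hi <- min(lo + chunk - 1L, nPix)
    X <- stats::mvfft(t(a[lo:hi, , drop = FALSE]))
    X[!keep, ] <- 0
    out[lo:hi, ] <- t(Re(stats::mvfft(X, inverse = TRUE)) / nT)
  }
  dim(out) <- d
  out
}

## Deepest pyramid usable for a frame so the coarsest level keeps at least
## `minSide` pixels on its short side.
.autoLevels <- function(h, w, minSide = 8L) {
  n <- 1L
  while (ceiling(min(h, w) / 2^n) >= minSide) n <- n + 1L
  n
}

#' Build a spatial pyramid of a frame
#'
#' In `"laplacian_pyramid"` mode, decomposes a frame into band-limited
#' levels (finest first) plus the Gaussian residual as the coarsest entry;
#' [collapsePyramid()] reconstructs the frame exactly. In `"gaussian_blur"`
#' mode the pyramid is a single lowpassed copy of the frame.
#'
#' @param frame Numeric matrix.
#' @param nLevels Number of levels (>= 1). With `nLevels = 1` the pyramid is
#'   the frame itself. The coarsest level must keep at least 4 px per side.
#' @param mode `"laplacian_pyramid"` or `"gaussian_blur"`.
#' @return List of matrices, finest level first.
#' @examples
#' f <- matrix(runif(64 * 64), 64, 64)
#' p <- buildPyramid(f, 4)
#' max(abs(collapsePyramid(p) - f))
#' @export
buildPyramid <- function(frame, nLevels,
                         mode = c("laplacian_pyramid", "gaussian_blur")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(frame), nLevels >= 1L)
  if (ceiling(min(dim(frame)) / 2^(nLevels - 1L)) < 4L)
    stop(sprintf("frame %d x %d is too small for %d pyramid levels",
                 nrow(frame), ncol(frame), nLevels))
  if (mode == "gaussian_blur")
    return(list(.blurStack(frame)[, , 1L]))
  if (nLevels == 1L)
    return(list(frame))
  g <- frame
  pyr <- vector("list", nLevels)
  for (i in seq_len(nLevels - 1L)) {
    nxt <- .downsampleStack(.blurStack(g))[, , 1L]
    pyr[[i]] <- g - .expandStack(nxt, nrow(g), ncol(g))[, , 1L]
    g <- nxt
  }
  pyr[[nLevels]] <- g
  pyr
}

#' @describeIn buildPyramid Reconstruct a frame from its Laplacian pyramid
#'   (exact inverse of `buildPyramid()` in `"laplacian_pyramid"` mode).
#' @param pyramid List of matrices as returned by `buildPyramid()`.
#' @export
collapsePyramid <- function(pyramid) {
  n <- length(pyramid)
  g <- pyramid[[n]]
  if (n > 1L)
    for (i in (n - 1L):1L)
      g <- pyramid[[i]] +
        .expandStack(g, nrow(pyramid[[i]]), ncol(pyramid[[i]]))[, , 1L]
  g
}

#' Magnify sub-band motion in a clip
#'
#' Eulerian magnification of a frame stack: each spatial location of each
#' pyramid level is temporally bandpass-filtered ([temporalIdealBandpass()]),
#' scaled by `alpha`, and added back to the original; the pyramid is then
#' collapsed and the result clamped to `[0, 1]`. Sub-pixel translations of
#' smooth patterns whose temporal frequency lies in the band appear magnified
#' by the effective motion gain `1 + alpha` (first-order approximation, valid
#' while the amplified excursion stays small against the pattern scale).
#'
#' A warning reports the fraction of clamped (saturated) samples when it
#' exceeds 1%.
#'
#' @param clip A [FrameStack].
#' @param band A [BandSpec] with `fHi <= fps(clip) / 2`.
#' @param params A [MagParams].
#' @return A [FrameStack] of the same shape and frame rate.
#' @seealso [trackClip()] for measuring the amplified motion,
#'   [GainSpec] for converting it back to physical units.
#' @export
magnifyClip <- function(clip, band, params = MagParams()) {
  stopifnot(is(clip, "FrameStack"), is(params, "MagParams"))
  .checkBand(band, clip@fps)
  a <- clip@frames
  d <- dim(a)
  if (params@alpha == 0)
    return(clip)

  nLevels <- params@nLevels
  if (is.na(nLevels))
    nLevels <- if (params@mode == "gaussian_blur") 1L
               else .autoLevels(d[1], d[2])
  if (ceiling(min(d[1], d[2]) / 2^(nLevels - 1L)) < 4L)
    stop(sprintf("frames %d x %d are too small for %d pyramid levels",
                 d[1], d[2], nLevels))

  if (params@mode == "gaussian_blur") {
    low <- .blurStack(a)
    out <- a + params@alpha * .bandpassStack(low, band, clip@fps)
  } else {
    ## Gaussian stack, then Laplacian levels, amplified finest-first.
    gauss <- vector("list", nLevels)
    gauss[[1L]] <- a
    for (i in seq_len(nLevels - 1L))
      gauss[[i + 1L]] <- .downsampleStack(.blurStack(gauss[[i]]))
    alphaLev <- rep(params@alpha, nLevels)
    if (params@attenuateFineLevels)
      alphaLev[1L] <- alphaLev[1L] * params@fineLevelScale

    processed <- vector("list", nLevels)
    for (i in seq_len(nLevels)) {
      lev <- if (i < nLevels) {
        gi <- dim(gauss[[i]])
        gauss[[i]] - .expandStack(gauss[[i + 1L]], gi[1], gi[2])
      } else {
        gauss[[i]]
      }
      processed[[i]] <- lev +
        alphaLev[i] * .bandpassStack(lev, band, clip@fps)
      if (i < nLevels) gauss[[i]] <- NA  # release
    }
    rm(gauss)
    out <- processed[[nLevels]]
    if (nLevels > 1L)
      for (i in (nLevels - 1L):1L) {
        gi <- dim(processed[[i]])
        out <- processed[[i]] + .expandStack(out, gi[1], gi[2])
        processed[[i]] <- NA
      }
    rm(processed)
  }

  cl <- .clamp01(out)
  if (cl$saturation > 0.01)
    warning(sprintf("%.1f%% of samples clamped to [0, 1] after magnification",
                    100 * cl$saturation))
  FrameStack(cl$a, clip@fps)
}
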
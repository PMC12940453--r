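## Combined X/Y amplitude spectrum of displacement series, in um/Hz.

#' Combined amplitude spectrum of a marker's motion
#'
#' One-sided DFT amplitude per axis, `a(k) = (2/N) |X_k|` for
#' `0 < k < N/2`, combined across the two axes per bin as the Euclidean
#' magnitude `c(k) = sqrt(a_x(k)^2 + a_y(k)^2)` and reported as a density
#' `c(k) / deltaF` in micrometres per Hz, with `deltaF = fps / N`. DC is
#' excluded (the series are zero-mean). For even `N` the Nyquist bin is
#' included with amplitude `sqrt(2) |X_{N/2}| / N`, which makes the
#' Parseval identity `rms^2 = sum(a^2) / 2` hold exactly for any series.
#'
#' An optional Hann window (with amplitude correction factor 2) reduces
#' leakage of off-bin tones for display; the unwindowed path is exact for
#' on-bin tones and is the quantitative convention.
#'
#' @param xSeries,ySeries [DisplacementSeries] of equal length and rate
#'   (the two in-plane axes of one marker). `ySeries = NULL` computes a
#'   single-axis spectrum.
#' @param window Apply a Hann window (default `FALSE`).
#' @param fMax Optional upper frequency cutoff in Hz for the returned grid.
#' @return An [AmplitudeSpectrum].
#' @examples
#' t <- (0:799) / 400
#' s <- DisplacementSeries(2 * sin(2 * pi * 40 * t), 400)
#' z <- DisplacementSeries(rep(c(0, 1e-12), 400), 400)
#' amplitudeSpectrum(s, z)
#' @export
amplitudeSpectrum <- function(xSeries, ySeries = NULL, window = FALSE,
                              fMax = NULL) {
  stopifnot(is(xSeries, "DisplacementSeries"))
  vx <- xSeries@values
  n <- length(vx)
  if (n < 16L)
    stop("need at least 16 samples for a spectrum")
  if (!is.null(ySeries)) {
    stopifnot(is(ySeries, "DisplacementSeries"))
    if (length(ySeries@values) != n)
      stop("x and y series must have equal length")
    if (ySeries@fps != xSeries@fps)
      stop("x and y series must have equal sampling rate")
  }
  fs <- xSeries@fps
  deltaF <- fs / n

  oneSided <- function(v) {
    if (window) {
      w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
      v <- v * w * 2   # Hann amplitude correction
    }
    X <- stats::fft(v)
    kMax <- if (n %% 2L == 0L) n %/% 2L else (n - 1L) %/% 2L
    k <- seq_len(kMax)        # bins 1 .. N/2 (or (N-1)/2 for odd N)
    a <- 2 / n * Mod(X[k + 1L])
    if (n %% 2L == 0L)        # Nyquist: power-preserving scaling
      a[kMax] <- sqrt(2) * Mod(X[kMax + 1L]) / n
    list(freq = k * deltaF, a = a)
  }

  sx <- oneSided(vx)
  comb <- if (is.null(ySeries)) sx$a
          else sqrt(sx$a^2 + oneSided(ySeries@values)$a^2)
  freq <- sx$freq
  if (!is.null(fMax)) {
    sel <- freq <= fMax
    freq <- freq[sel]
    comb <- comb[sel]
  }
  new("AmplitudeSpectrum", freqs = freq, density = comb / deltaF,
      deltaF = deltaF)
}
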
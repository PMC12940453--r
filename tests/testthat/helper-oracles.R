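## Shared fixtures and independent oracles for the test suite.
## Everything is generated in code; no binary fixtures.

## Independent brute-force bandpass oracle: per-bin DFT computed as an
## explicit O(N^2) sum, masked, and inverted as an explicit sum. Kept free
## of stats::fft so it can certify the fft-based filter path.
dftBandpassOracle <- function(x, fLo, fHi, fs) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  X <- as.vector(W %*% x)
  f <- k * fs / n
  f <- pmin(f, fs - f)
  X[!(f >= fLo & f <= fHi)] <- 0
  Re(as.vector(Conj(W) %*% X)) / n
}

## Small scene: one cross marker centered in a compact frame.
tinyScene <- function(tones = list(), widthPx = 48, heightPx = 48,
                      fps = 200, durationS = 0.25, noiseSigma = 0,
                      pixelPitchMm = c(0.49, 0.46), seed = 1, ...) {
  SceneConfig(widthPx = widthPx, heightPx = heightPx, fps = fps,
              durationS = durationS, noiseSigma = noiseSigma,
              pixelPitchMm = pixelPitchMm,
              markers = list(MarkerSpec(
                centerPx = c(widthPx / 2, heightPx / 2), tones = tones)),
              seed = seed, ...)
}

## Track the single marker of a tiny-scene clip.
trackTiny <- function(clip, cfg, searchRadiusPx = 4) {
  tpl <- makeTemplate(cfg@markers[[1]], cfg@pixelPitchMm)
  init <- matrix(cfg@markers[[1]]@centerPx, ncol = 2)
  trackClip(clip, init, tpl, searchRadiusPx = searchRadiusPx)[[1]]
}

## Zero-mean displacement-like series: sum of tones plus white noise.
syntheticSeries <- function(n, fps, tones = list(c(2.5, 40, 0)),
                            noiseSd = 0.3, seed = 1) {
  t <- (seq_len(n) - 1) / fps
  v <- 0
  for (tn in tones)
    v <- v + tn[1] * sin(2 * pi * tn[2] * t + tn[3])
  set.seed(seed)
  v <- v + rnorm(n, sd = noiseSd)
  DisplacementSeries(v, fps)
}
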
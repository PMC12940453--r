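test_that("ideal bandpass matches closed forms and removes DC", {
  fs <- 200
  t <- (0:199) / fs
  band <- BandSpec(10, 100)

  expect_equal(temporalIdealBandpass(rep(0.7, 200), band, fs), rep(0, 200))

  s <- 0.5 + 0.001 * sin(2 * pi * 30 * t)
  out <- temporalIdealBandpass(s, band, fs)
  expect_lt(max(abs(out - 0.001 * sin(2 * pi * 30 * t))), 1e-9)
  expect_lt(abs(mean(out)), 1e-12)

  ## on-bin tone below the band is removed entirely
  s5 <- 0.5 + 0.001 * sin(2 * pi * 5 * t)
  expect_lt(max(abs(temporalIdealBandpass(s5, band, fs))), 1e-9)

  expect_error(temporalIdealBandpass(s, BandSpec(10, 150), fs), "Nyquist")
  expect_error(temporalIdealBandpass(s[1:3], band, fs), "4 time samples")
})

test_that("fft-based bandpass agrees with a brute-force per-bin DFT mask", {
  set.seed(42)
  fs <- 128
  band <- BandSpec(8, 40)
  for (n in c(31, 64)) {
    for (i in 1:25) {
      x <- rnorm(n)
      expect_lt(max(abs(temporalIdealBandpass(x, band, fs) -
                          dftBandpassOracle(x, 8, 40, fs))), 1e-9)
    }
  }
})

test_that("Laplacian pyramid reconstructs exactly and degenerates sensibly", {
  set.seed(7)
  f <- matrix(runif(64 * 64), 64, 64)

  p1 <- buildPyramid(f, 1)
  expect_identical(p1[[1]], f)
  expect_identical(collapsePyramid(p1), f)

  p4 <- buildPyramid(f, 4)
  expect_length(p4, 4)
  expect_lt(max(abs(collapsePyramid(p4) - f)), 1e-6)

  ## constant frame: all detail levels vanish
  pc <- buildPyramid(matrix(0.3, 64, 64), 4)
  for (i in 1:3) expect_lt(max(abs(pc[[i]])), 1e-12)
  expect_equal(pc[[4]], matrix(0.3, 8, 8), tolerance = 1e-12)

  expect_error(buildPyramid(matrix(0, 8, 8), 4), "too small")
})

test_that("magnification amplifies in-band intensity tones by alpha", {
  fs <- 200
  nT <- 200
  t <- (seq_len(nT) - 1) / fs
  a <- array(0.5, dim = c(16, 16, nT))
  a[8, 8, ] <- 0.5 + 0.001 * sin(2 * pi * 30 * t)
  clip <- FrameStack(a, fs)
  band <- BandSpec(10, 90)

  out <- magnifyClip(clip, band, MagParams(alpha = 100))
  series <- frames(out)[8, 8, ] - 0.5
  amp <- 2 / nT * Mod(fft(series))[30 / (fs / nT) + 1]
  ## output = original + alpha * bandpassed => tone amplitude (1 + alpha) * a0
  expect_equal(amp, 0.101, tolerance = 0.01)

  ## alpha = 0 is the identity
  out0 <- magnifyClip(clip, band, MagParams(alpha = 0))
  expect_lt(max(abs(frames(out0) - a)), 1e-6)
})

test_that("amplified motion is linear in the input amplitude", {
  ## base amplitude 0.98 um = 0.002 px at 0.49 mm/px, so the amplified
  ## excursion (~0.2-0.4 px) stays well inside the first-order regime
  measured <- vapply(c(1, 2), function(scl) {
    cfg <- tinyScene(tones = list(Tone(scl * 0.98, 25)), fps = 200,
                     durationS = 0.5, seed = 5)
    sim <- simulateClip(cfg)
    mag <- magnifyClip(sim$clip, BandSpec(10, 90), MagParams(alpha = 100))
    tr <- trackTiny(mag, cfg)
    x <- positions(tr)[, 1]
    sqrt(2) * sd(x)   # sinusoid amplitude in px
  }, numeric(1))
  expect_equal(measured[2] / measured[1], 2, tolerance = 0.02)
  ## motion gain ~ (1 + alpha) within 10%
  expect_equal(measured[1] / 0.002, 101, tolerance = 0.1)
})

test_that("out-of-band clips pass through magnification unchanged", {
  cfg <- tinyScene(tones = list(Tone(2.45, 80)), fps = 200, durationS = 0.5,
                   seed = 6)
  sim <- simulateClip(cfg)
  out <- magnifyClip(sim$clip, BandSpec(10, 40), MagParams(alpha = 100))
  expect_lt(max(abs(frames(out) - frames(sim$clip))), 1e-6)
})

test_that("heavy saturation is reported", {
  fs <- 100
  nT <- 100
  t <- (seq_len(nT) - 1) / fs
  a <- array(rep(0.5 + 0.05 * sin(2 * pi * 20 * t), each = 16 * 16),
             dim = c(16, 16, nT))
  expect_warning(magnifyClip(FrameStack(a, fs), BandSpec(10, 45),
                             MagParams(alpha = 100)),
                 "clamped")
})
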
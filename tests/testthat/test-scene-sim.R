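test_that("cross rasterization is exact under oversampling, mirroring and integer shifts", {
  sp <- MarkerSpec(centerPx = c(32, 32))

  ## area-weighted rasterization has converged by supersample 8
  p8 <- renderCross(sp, c(0.3, 0.2), supersample = 8)
  p64 <- renderCross(sp, c(0.3, 0.2), supersample = 64)
  expect_lt(max(abs(p64 - p8)), 1e-2)

  ## symmetric cross: +0.5 px offset mirrors the -0.5 px patch
  a <- renderCross(sp, c(0.5, 0))
  b <- renderCross(sp, c(-0.5, 0))
  expect_lt(max(abs(a - b[, ncol(b):1])), 1e-12)

  ## integer offset is a pure pixel shift
  s1 <- renderCross(sp, c(1, 0), patchSize = 31)
  s0 <- renderCross(sp, c(0, 0), patchSize = 31)
  expect_equal(s1[, 2:31], s0[, 1:30])

  ## values are coverages
  expect_gte(min(p8), 0)
  expect_lte(max(p8), 1)
})

test_that("rendered sub-pixel centers are recovered by intensity moments", {
  sp <- MarkerSpec(centerPx = c(32, 32))
  for (off in list(c(0.25, -0.4), c(-0.13, 0.37), c(0.49, 0.49))) {
    p <- renderCross(sp, off, supersample = 8)
    c0 <- (nrow(p) + 1) / 2
    cx <- sum(col(p) * p) / sum(p)
    cy <- sum(row(p) * p) / sum(p)
    expect_lt(abs(cx - (c0 + off[1])), 0.02)
    expect_lt(abs(cy - (c0 + off[2])), 0.02)
  }
})

test_that("rendering fails loudly when the cross leaves its patch", {
  sp <- MarkerSpec(id = "noseMarker", centerPx = c(10, 10))
  expect_error(renderCross(sp, c(0, 0), patchSize = 15), "noseMarker")
})

test_that("simulated clips are deterministic with exact ground truth", {
  cfg <- tinyScene(tones = list(Tone(2.5, 40)), fps = 320, durationS = 0.25,
                   noiseSigma = 0.004, seed = 3)
  s1 <- simulateClip(cfg)
  s2 <- simulateClip(cfg)
  expect_identical(frames(s1$clip), frames(s2$clip))
  expect_identical(s1$truth, s2$truth)
  expect_identical(fps(s1$clip), 320)

  ## sinusoid evaluation: frame at t = 1/(4*40) s carries the full amplitude
  k <- 320 / (4 * 40) + 1   # t = (k-1)/fps
  raw <- 2.5 * sin(2 * pi * 40 * (s1$truth$frame - 1) / 320)
  expect_equal(s1$truth$dxUm, raw - mean(raw), tolerance = 1e-12)
  expect_equal(s1$truth$dxUm[k] - s1$truth$dxUm[1], 2.5, tolerance = 1e-9)

  ## ground truth is re-centered on the clip mean
  expect_lt(abs(mean(s1$truth$dxUm)), 1e-9)
  expect_lt(abs(mean(s1$truth$dyUm)), 1e-9)
  expect_equal(s1$truth$dxPx * 0.49 * 1000, s1$truth$dxUm, tolerance = 1e-9)
})

test_that("still scenes without noise are bit-identical across frames", {
  cfg <- tinyScene(fps = 100, durationS = 0.05, noiseSigma = 0)
  s <- simulateClip(cfg)
  a <- frames(s$clip)
  for (k in 2:dim(a)[3])
    expect_identical(a[, , k], a[, , 1])
  expect_true(all(s$truth$dxUm == 0))
})

test_that("aliased tones and out-of-frame markers are rejected", {
  expect_error(simulateClip(tinyScene(tones = list(Tone(1, 150)), fps = 200)),
               "alias")
  cfg <- SceneConfig(widthPx = 32, heightPx = 32, fps = 100, durationS = 0.05,
                     markers = list(MarkerSpec(id = "edge",
                                               centerPx = c(5, 16))))
  expect_error(simulateClip(cfg), "edge")
})

test_that("condition pairs share everything except marker motion", {
  cfg <- tinyScene(fps = 200, durationS = 0.2, noiseSigma = 0.004, seed = 9)
  pair <- makeConditionPair(cfg, list(Tone(2.5 * sqrt(2), 40)))

  ## idle ground truth is exactly zero without jitter
  expect_true(all(pair$idle$truth$dxUm == 0))

  ## scan ground-truth RMS of a single tone is A / sqrt(2)
  rms <- sqrt(mean(pair$scan$truth$dxUm^2))
  expect_equal(rms, 2.5, tolerance = 0.02)

  ## frames differ only near the marker (shared texture and noise elsewhere)
  d <- abs(frames(pair$scan$clip) - frames(pair$idle$clip))
  changed <- which(apply(d, c(1, 2), max) > 1e-12, arr.ind = TRUE)
  ctr <- cfg@markers[[1]]@centerPx
  halfSpan <- cfg@markers[[1]]@armLengthMm / min(cfg@pixelPitchMm) / 2 + 3
  expect_true(all(abs(changed[, "row"] - ctr[2]) <= halfSpan))
  expect_true(all(abs(changed[, "col"] - ctr[1]) <= halfSpan))
})

test_that("idle jitter is reproducible and recorded in the ground truth", {
  cfg <- tinyScene(fps = 200, durationS = 0.1, seed = 4)
  s1 <- simulateClip(cfg, jitterSdUm = 1)
  s2 <- simulateClip(cfg, jitterSdUm = 1)
  expect_identical(s1$truth, s2$truth)
  expect_gt(sd(s1$truth$dxUm), 0.5)
})
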
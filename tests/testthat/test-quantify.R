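mkTrack <- function(x, y = rep(10, length(x)), fps = 100, id = "m1") {
  Track(id, cbind(x = x, y = y), rep(1, length(x)), fps)
}

test_that("displacement conversion follows the pitch/gain arithmetic", {
  ## direct arithmetic oracle: 0.001 px * 0.49 mm/px * 1000 / 101 um
  tr <- mkTrack(c(10, 10.001, 10, 9.999))
  ser <- toDisplacement(tr, Calibration(0.49, 0.46), GainSpec(101))
  expect_equal(values(ser$x),
               c(0, 0.001, 0, -0.001) * 0.49 * 1000 / 101,
               tolerance = 1e-9)

  ## constant positions give an all-zero series
  expect_true(all(values(toDisplacement(mkTrack(rep(3, 10)))$x) == 0))

  ## unit conversion: 0.001 px at 1 mm/px, g = 1 -> 1 um
  ser1 <- toDisplacement(mkTrack(c(10, 10.002)), Calibration(1, 1),
                         GainSpec(1))
  expect_equal(values(ser1$x), c(-1, 1), tolerance = 1e-9)

  ## metrics scale linearly with pitch and inversely with gain
  tr2 <- mkTrack(10 + cumsum(rnorm(50, sd = 0.01)))
  r1 <- rmsDisplacement(toDisplacement(tr2, Calibration(0.5, 0.5),
                                       GainSpec(2))$x)
  r2 <- rmsDisplacement(toDisplacement(tr2, Calibration(1.0, 1.0),
                                       GainSpec(2))$x)
  r3 <- rmsDisplacement(toDisplacement(tr2, Calibration(0.5, 0.5),
                                       GainSpec(4))$x)
  expect_equal(r2 / r1, 2, tolerance = 1e-9)
  expect_equal(r1 / r3, 2, tolerance = 1e-9)
})

test_that("segmentation re-centers per condition and keeps every frame", {
  fps <- 100
  v <- seq(-1, 1, length.out = 200)   # zero-mean ramp
  ser <- DisplacementSeries(v, fps)

  one <- segmentSeries(ser, SegmentPlan("all", 0, 2))
  expect_equal(values(one$all), v - mean(v), tolerance = 1e-12)

  halves <- segmentSeries(ser, SegmentPlan(c("a", "b"), c(0, 1), c(1, 2)))
  expect_lt(abs(mean(values(halves$a))), 1e-12)
  expect_lt(abs(mean(values(halves$b))), 1e-12)
  expect_length(values(halves$a), 100)

  ## the reference 87 s acquisition at 100 Hz: 1200/2500/2500/2500 frames
  long <- DisplacementSeries(sin(2 * pi * 5 * (0:8699) / 100), 100)
  segs <- segmentSeries(long, acquisitionSegmentPlan())
  expect_equal(vapply(segs, function(s) length(values(s)), numeric(1)),
               c(b0 = 1200, dir1 = 2500, dir2 = 2500, dir3 = 2500))

  ## re-adding the segment means reproduces the unsegmented series
  means <- c(mean(v[1:100]), mean(v[101:200]))
  rebuilt <- c(values(halves$a) + means[1], values(halves$b) + means[2])
  expect_equal(rebuilt, v - mean(v), tolerance = 1e-12)

  expect_error(segmentSeries(ser, SegmentPlan("late", 5, 6)), "fewer than 2")
})

test_that("RMS and peak-to-peak follow their closed forms", {
  expect_equal(rmsDisplacement(c(1, -1, 1, -1)), 1)
  expect_equal(peakToPeak(c(1, -1, 1, -1)), 2)

  expect_equal(rmsDisplacement(c(0.5, -0.5, 1.5, -1.5)),
               sqrt(mean(c(0.5, -0.5, 1.5, -1.5)^2)))
  expect_equal(peakToPeak(c(0.5, -0.5, 1.5, -1.5)), 3)

  ## densely sampled sinusoid of amplitude 2: rms -> sqrt(2), p-p -> 4
  t <- (0:1999) / 1000
  s <- 2 * sin(2 * pi * 20 * t)
  expect_equal(rmsDisplacement(s), 2 / sqrt(2), tolerance = 0.01)
  expect_equal(peakToPeak(s), 4, tolerance = 0.02)
})

test_that("pooled summaries use the midpoint median and full range", {
  p <- poolSummary(c(2.32, 2.24, 3.16, 2.82))
  expect_equal(p$median, 2.57)
  expect_equal(p$min, 2.24)
  expect_equal(p$max, 3.16)
  expect_equal(p$n, 4)

  expect_equal(poolSummary(5)$median, 5)
  expect_equal(poolSummary(c(1, 2, 3))$median, 2)
  expect_error(poolSummary(numeric()), "at least one")
})

test_that("metric tables carry one row per marker, axis and condition", {
  tracks <- list(mkTrack(10 + sin(1:100 / 5) * 0.01, fps = 100, id = "a"),
                 mkTrack(20 + cos(1:100 / 7) * 0.01, fps = 100, id = "b"))
  plan <- SegmentPlan(c("s1", "s2"), c(0, 0.5), c(0.5, 1))
  m <- displacementMetrics(tracks, Calibration(0.49, 0.46), GainSpec(101),
                           plan)
  expect_equal(nrow(m), 2 * 2 * 2)
  expect_true(all(m$ppUm >= m$rmsUm))
  expect_true(all(m$rmsUm >= 0))
})

test_that("the pipeline recovers a known tone amplitude end to end", {
  ## true amplitude 2.45 um = 0.005 px at 0.49 mm/px, amplified 101x
  A <- 2.45
  cfg <- SceneConfig(widthPx = 64, heightPx = 64, fps = 500, durationS = 1,
                     pixelPitchMm = c(0.49, 0.49), noiseSigma = 0.005,
                     markers = list(MarkerSpec(centerPx = c(32, 32),
                       tones = list(Tone(A, 40)))), seed = 21)
  sim <- simulateClip(cfg)
  mag <- suppressWarnings(
    magnifyClip(sim$clip, BandSpec(10, 100), MagParams(alpha = 100)))
  tr <- trackClip(mag, cbind(32, 32),
                  makeTemplate(cfg@markers[[1]], c(0.49, 0.49)))[[1]]
  ser <- toDisplacement(tr, Calibration(0.49, 0.49), GainSpec(101))
  expect_equal(rmsDisplacement(ser$x), A / sqrt(2), tolerance = 0.2)
})
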
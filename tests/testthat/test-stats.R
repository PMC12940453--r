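test_that("split-half RMS pairs agree on stationary series", {
  expect_equal(unlist(splitHalfPairs(c(1, -1, 1, -1))[1, 1:2],
                      use.names = FALSE), c(1, 1))

  ## stationary sinusoid with whole cycles per half
  s <- syntheticSeries(1000, 500, tones = list(c(2, 40, 0)), noiseSd = 0)
  p <- splitHalfPairs(s)
  expect_equal(p$rmsFirst, p$rmsSecond, tolerance = 0.01)
  expect_equal(p$markerId, "m1")

  ## amplitude ramping 2x across the clip
  t <- (0:999) / 500
  ramp <- (1 + t / max(t)) * sin(2 * pi * 40 * t)
  pr <- splitHalfPairs(DisplacementSeries(ramp, 500))
  expect_equal(pr$rmsSecond / pr$rmsFirst,
               sqrt(mean((1.5 + 0.5 * seq(0, 1, length.out = 500))^2)) /
                 sqrt(mean((1 + 0.5 * seq(0, 1, length.out = 500))^2)),
               tolerance = 0.1)
  expect_gt(pr$rmsSecond / pr$rmsFirst, 1.3)

  expect_error(splitHalfPairs(c(1, 2)), "at least 4")
})

test_that("Bland-Altman matches hand-computed oracles and sign convention", {
  ## identical pairs
  ba0 <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$meanDiff, 0)
  expect_equal(ba0$loaHigh - ba0$loaLow, 0)

  ## single pair (1.0, 0.9): d = 100 * 0.1 / 0.95
  ba1 <- blandAltman(1.0, 0.9)
  expect_equal(ba1$meanDiff, 100 * 0.1 / 0.95, tolerance = 1e-9)
  expect_true(is.na(ba1$loaLow))

  ## hand-computed: d = {0, 0, 20}
  ba <- blandAltman(c(1, 2, 1.1), c(1, 2, 0.9))
  expect_equal(ba$meanDiff, 20 / 3, tolerance = 1e-9)
  expect_equal(ba$sd, sd(c(0, 0, 20)), tolerance = 1e-9)
  expect_equal(ba$loaLow, 20 / 3 - 1.96 * sd(c(0, 0, 20)), tolerance = 1e-9)

  ## first-minus-second: swapping the order negates mean and mirrors LoA
  baR <- blandAltman(c(1, 2, 0.9), c(1, 2, 1.1))
  expect_equal(baR$meanDiff, -ba$meanDiff, tolerance = 1e-9)
  expect_equal(baR$loaLow, -ba$loaHigh, tolerance = 1e-9)
  expect_equal(baR$loaHigh, -ba$loaLow, tolerance = 1e-9)

  expect_error(blandAltman(1, -1), "zero mean")
})

test_that("block bootstrap CIs behave and reproduce under a seed", {
  s <- syntheticSeries(800, 400, noiseSd = 0.3, seed = 2)
  spec <- ResamplingSpec(nBoot = 300, nPerm = 199, blockLenFrames = 40,
                         seed = 7)

  ## a vs a: CI contains 0
  ci <- blockBootstrapCi(s, s, spec)
  expect_lte(ci$ciLo, 0)
  expect_gte(ci$ciHi, 0)
  expect_equal(ci$rmsDiff, 0)

  ## determinism
  ci2 <- blockBootstrapCi(s, s, spec)
  expect_identical(ci, ci2)

  ## 3x amplitude: CI excludes 0 across seeds
  excl <- vapply(1:20, function(seed) {
    a <- syntheticSeries(600, 400, noiseSd = 0.3, seed = seed)
    b <- DisplacementSeries(3 * values(a), 400)
    ci <- blockBootstrapCi(b, a, ResamplingSpec(nBoot = 300, nPerm = 199,
                                                blockLenFrames = 40,
                                                seed = seed))
    ci$ciLo > 0 || ci$ciHi < 0
  }, logical(1))
  expect_gte(mean(excl), 0.95)

  expect_error(blockBootstrapCi(rnorm(50), rnorm(800), spec), "4 blocks")
})

test_that("block permutation p-values are valid, powerful and reproducible", {
  a <- syntheticSeries(600, 400, noiseSd = 0.3, seed = 3)
  b <- DisplacementSeries(3 * values(a), 400)
  spec <- ResamplingSpec(nBoot = 100, nPerm = 499, blockLenFrames = 40,
                         seed = 11)

  res <- permutationTestRms(b, a, spec)
  expect_lte(res$pTwoSided, 0.01)
  expect_gte(res$pTwoSided, 1 / (spec@nPerm + 1))

  res2 <- permutationTestRms(b, a, spec)
  expect_identical(res, res2)

  ## p floor: identical series give p close to 1, never 0
  resEq <- permutationTestRms(a, a, spec)
  expect_gt(resEq$pTwoSided, 0.5)
})
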
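## Synthetic scene generation: cross markers under known sub-pixel motion,
## with exact ground truth, on a textured noisy background.

## Per-pixel coverage of a 1D interval |coord - center| <= halfLen: each of
## the `s` subsample cells per pixel contributes the fraction of its width
## covered by the interval (area-weighted box filtering; exact for the
## axis-aligned edges of a cross). Pixel centers sit at integer coordinates.
.coverage1d <- function(nPx, center, halfLen, s) {
  sub <- outer((seq_len(s) - (s + 1) / 2) / s, seq_len(nPx), "+")
  lo <- pmax(sub - 1 / (2 * s), center - halfLen)
  hi <- pmin(sub + 1 / (2 * s), center + halfLen)
  colMeans(pmax(hi - lo, 0) * s)
}

## Coverage field of an axis-aligned cross (union of two bars) on an
## nRow x nCol pixel grid. The union decomposes separably:
## cross = Hbar + Vbar - (Hbar ∩ Vbar), each term an outer product of 1D
## coverages, so supersampled box filtering costs O(n * s) not O((n s)^2).
.crossCoverage <- function(nRow, nCol, cx, cy, halfLenX, halfWidX,
                           halfLenY, halfWidY, s) {
  mxL <- .coverage1d(nCol, cx, halfLenX, s)
  mxW <- .coverage1d(nCol, cx, halfWidX, s)
  myL <- .coverage1d(nRow, cy, halfLenY, s)
  myW <- .coverage1d(nRow, cy, halfWidY, s)
  outer(myW, mxL) + outer(myL, mxW) - outer(myW, mxW)
}

## Cross dimensions in pixels along each image axis.
.crossDimsPx <- function(spec, pixelPitchMm) {
  list(
    halfLenX = spec@armLengthMm / pixelPitchMm[1] / 2,
    halfWidX = spec@armWidthMm / pixelPitchMm[1] / 2,
    halfLenY = spec@armLengthMm / pixelPitchMm[2] / 2,
    halfWidY = spec@armWidthMm / pixelPitchMm[2] / 2
  )
}

#' Render a cross marker patch at a sub-pixel offset
#'
#' Rasterizes the cross described by `spec` into a square patch by
#' supersampled, box-filtered (area-weighted) anti-aliasing, which makes
#' sub-pixel positions exactly representable in the rendered intensities.
#' The cross center sits at the patch center plus `offsetPx`.
#'
#' @param spec A [MarkerSpec].
#' @param offsetPx Numeric `(dx, dy)` sub-pixel offset of the cross center
#'   from the patch center, in pixels. Offsets beyond one pixel are legal.
#' @param supersample Integer oversampling factor per axis (>= 4).
#' @param pixelPitchMm `(x, y)` physical pixel size in mm/pixel, used to
#'   convert the physical arm dimensions to pixels.
#' @param patchSize Odd patch side length in pixels; by default the smallest
#'   odd size containing the cross plus a 2 px margin.
#' @return Numeric `patchSize x patchSize` coverage matrix in `[0, 1]`
#'   (1 = pixel fully covered by the marker). The marker's appearance in a
#'   scene is `background - contrast * coverage`.
#' @seealso [simulateClip()], [makeTemplate()]
#' @examples
#' p <- renderCross(MarkerSpec(), offsetPx = c(0.3, -0.2))
#' range(p)
#' @export
renderCross <- function(spec, offsetPx = c(0, 0), supersample = 8,
                        pixelPitchMm = c(0.49, 0.46), patchSize = NULL) {
  stopifnot(is(spec, "MarkerSpec"), supersample >= 4)
  dims <- .crossDimsPx(spec, pixelPitchMm)
  if (is.null(patchSize)) {
    half <- ceiling(max(dims$halfLenX, dims$halfLenY) +
                      max(abs(offsetPx)) + 2)
    patchSize <- 2L * half + 1L
  }
  if (patchSize %% 2L == 0L)
    stop("'patchSize' must be odd")
  c0 <- (patchSize + 1) / 2
  cx <- c0 + offsetPx[1]
  cy <- c0 + offsetPx[2]
  if (cx - dims$halfLenX < 0.5 || cx + dims$halfLenX > patchSize + 0.5 ||
      cy - dims$halfLenY < 0.5 || cy + dims$halfLenY > patchSize + 0.5)
    stop(sprintf("cross of marker '%s' extends beyond its %d px patch",
                 spec@id, patchSize))
  .crossCoverage(patchSize, patchSize, cx, cy,
                 dims$halfLenX, dims$halfWidX,
                 dims$halfLenY, dims$halfWidY,
                 as.integer(supersample))
}

## Per-frame physical tone displacement (um) of a marker along one axis.
.toneSeries <- function(tones, axis, t, fps) {
  out <- numeric(length(t))
  for (tone in tones) {
    if (tone@frequencyHz >= fps / 2)
      stop(sprintf(
        "tone at %g Hz would alias at %g fps (needs f < fps/2)",
        tone@frequencyHz, fps))
    if (tone@axis == axis) {
      active <- t >= tone@startS & t < tone@endS
      out <- out + active * tone@amplitudeUm *
        sin(2 * pi * tone@frequencyHz * t + tone@phaseRad)
    }
  }
  out
}

#' Simulate a high-speed clip of vibrating cross markers
#'
#' Renders every frame of a synthetic clip: a static, seeded background
#' texture; each marker drawn dark-on-light at its tone-driven sub-pixel
#' position; i.i.d. Gaussian sensor noise per frame; values clamped to
#' `[0, 1]`. The exact per-frame displacement of every marker is returned as
#' ground truth, re-centered on the clip-mean position. Identical
#' configurations (including the seed) give bit-identical results.
#'
#' @param config A [SceneConfig].
#' @param jitterSdUm Optional white Gaussian positional jitter SD in
#'   micrometres added to every marker on both axes (default 0 = off),
#'   emulating low-level inherent motion of an idle scene. Drawn from a
#'   seed derived from `config@seed` so that enabling jitter does not shift
#'   the texture/noise stream.
#' @return A list with elements `clip` (a [FrameStack]) and `truth` (a
#'   data frame with columns `frame`, `markerId`, `dxUm`, `dyUm`, `dxPx`,
#'   `dyPx`: exact displacements relative to the clip-mean position).
#' @examples
#' cfg <- SceneConfig(widthPx = 48, heightPx = 48, fps = 200, durationS = 0.1,
#'                    markers = list(MarkerSpec(centerPx = c(24, 24))))
#' sim <- simulateClip(cfg)
#' sim$clip
#' @export
simulateClip <- function(config, jitterSdUm = 0) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  h <- config@heightPx
  w <- config@widthPx
  nT <- as.integer(round(config@fps * config@durationS))
  if (nT < 2L)
    stop("clip must contain at least 2 frames")
  t <- (seq_len(nT) - 1L) / config@fps
  pitch <- config@pixelPitchMm
  nM <- length(config@markers)
  if (nM == 0L)
    stop("the scene needs at least one marker")

  ## Per-marker physical motion (um), then pixels; jitter from derived seed.
  dxUm <- dyUm <- matrix(0, nT, nM)
  for (m in seq_len(nM)) {
    tones <- config@markers[[m]]@tones
    dxUm[, m] <- .toneSeries(tones, "horizontal", t, config@fps)
    dyUm[, m] <- .toneSeries(tones, "vertical", t, config@fps)
  }
  if (jitterSdUm > 0) {
    jit <- withSeed(config@seed + 1000003L,
                    stats::rnorm(2L * nT * nM, sd = jitterSdUm))
    dxUm <- dxUm + matrix(jit[seq_len(nT * nM)], nT, nM)
    dyUm <- dyUm + matrix(jit[nT * nM + seq_len(nT * nM)], nT, nM)
  }
  dxPx <- dxUm / 1000 / pitch[1]
  dyPx <- dyUm / 1000 / pitch[2]

  ## Patch geometry per marker.
  geom <- vector("list", nM)
  for (m in seq_len(nM)) {
    spec <- config@markers[[m]]
    dims <- .crossDimsPx(spec, pitch)
    half <- ceiling(max(dims$halfLenX, dims$halfLenY) +
                      max(abs(c(dxPx[, m], dyPx[, m]))) + 2)
    ax <- round(spec@centerPx[1])
    ay <- round(spec@centerPx[2])
    if (ay - half < 1 || ay + half > h || ax - half < 1 || ax + half > w)
      stop(sprintf("marker '%s' (with its motion) does not fit in the frame",
                   spec@id))
    geom[[m]] <- list(spec = spec, dims = dims, half = half, ax = ax, ay = ay,
                      rows = (ay - half):(ay + half),
                      cols = (ax - half):(ax + half))
  }

  arr <- withSeed(config@seed, {
    ## Static background texture: blurred white noise, fixed SD.
    bg <- matrix(config@backgroundLevel, h, w)
    if (config@textureAmp > 0) {
      tex <- matrix(stats::rnorm(h * w), h, w)
      tex <- .blurStack(.blurStack(tex))[, , 1L]
      bg <- bg + tex / stats::sd(tex) * config@textureAmp
    }
    a <- array(0, dim = c(h, w, nT))
    for (k in seq_len(nT)) {
      fr <- bg
      for (m in seq_len(nM)) {
        g <- geom[[m]]
        p <- 2L * g$half + 1L
        cx <- g$half + 1 + (g$spec@centerPx[1] + dxPx[k, m] - g$ax)
        cy <- g$half + 1 + (g$spec@centerPx[2] + dyPx[k, m] - g$ay)
        cov <- .crossCoverage(p, p, cx, cy,
                              g$dims$halfLenX, g$dims$halfWidX,
                              g$dims$halfLenY, g$dims$halfWidY,
                              config@supersample)
        fr[g$rows, g$cols] <- fr[g$rows, g$cols] - g$spec@contrast * cov
      }
      if (config@noiseSigma > 0)
        fr <- fr + stats::rnorm(h * w, sd = config@noiseSigma)
      a[, , k] <- fr
    }
    a
  })
  arr <- .clamp01(arr)$a

  truth <- data.frame(
    frame = rep(seq_len(nT), nM),
    markerId = rep(vapply(config@markers, function(s) s@id, character(1)),
                   each = nT),
    dxUm = as.vector(sweep(dxUm, 2, colMeans(dxUm))),
    dyUm = as.vector(sweep(dyUm, 2, colMeans(dyUm))),
    dxPx = as.vector(sweep(dxPx, 2, colMeans(dxPx))),
    dyPx = as.vector(sweep(dyPx, 2, colMeans(dyPx))),
    stringsAsFactors = FALSE
  )
  list(clip = FrameStack(arr, config@fps), truth = truth)
}

#' Generate a matched idle / scanning clip pair
#'
#' Produces two clips from the same scene configuration and seed: an "idle"
#' clip whose markers carry no tones (sensor noise plus optional low-level
#' positional jitter only) and a "scan" clip whose markers vibrate with
#' `scanTones`. Background texture and sensor noise realizations are
#' identical between the two, so the clips differ only where marker
#' intensity differs.
#'
#' @param config A [SceneConfig]; its markers' own tones are ignored.
#' @param scanTones List of [Tone] objects applied to every marker in the
#'   scan clip, or a list of such lists (one per marker).
#' @param jitterSdUm Idle-condition positional jitter SD in micrometres
#'   (default 0 = off; keeps the idle ground truth exactly zero).
#' @return A list with elements `idle` and `scan`, each as returned by
#'   [simulateClip()].
#' @export
makeConditionPair <- function(config, scanTones, jitterSdUm = 0) {
  stopifnot(is(config, "SceneConfig"))
  nM <- length(config@markers)
  perMarker <- length(scanTones) == nM &&
    all(vapply(scanTones, is.list, logical(1)))
  idleCfg <- config
  scanCfg <- config
  for (m in seq_len(nM)) {
    idleCfg@markers[[m]]@tones <- list()
    scanCfg@markers[[m]]@tones <-
      if (perMarker) scanTones[[m]] else scanTones
  }
  list(idle = simulateClip(idleCfg, jitterSdUm = jitterSdUm),
       scan = simulateClip(scanCfg))
}
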
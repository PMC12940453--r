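## Marker detection and sub-pixel tracking by normalized cross-correlation
## with paraboloid refinement, plus pixel-pitch calibration.

#' Build a matching template from a marker specification
#'
#' Renders the noise-free appearance of a cross marker (background 1, dark
#' cross) into an odd-sized patch for use as the normalized
#' cross-correlation template.
#'
#' @param spec A [MarkerSpec].
#' @param pixelPitchMm `(x, y)` pixel pitch in mm/pixel.
#' @param supersample Rasterization oversampling factor.
#' @return A [Template].
#' @export
makeTemplate <- function(spec, pixelPitchMm = c(0.49, 0.46),
                         supersample = 8) {
  cov <- renderCross(spec, c(0, 0), supersample, pixelPitchMm)
  new("Template", patch = 1 - spec@contrast * cov,
      armLengthMm = spec@armLengthMm, armWidthMm = spec@armWidthMm,
      pixelPitchMm = as.numeric(pixelPitchMm))
}

## Normalized cross-correlation of an image region with a zero-mean,
## unit-norm template vector. Constant regions score 0.
.nccOne <- function(patchVec, tplZ, tplNorm) {
  pz <- patchVec - mean(patchVec)
  d <- sqrt(sum(pz * pz))
  if (d < 1e-12) return(0)
  sum(pz * tplZ) / (d * tplNorm)
}

## NCC map of `img` against `tpl` over all valid placements (or a subset of
## top-left anchors). Returns the map plus the (x, y) center coordinate of
## the template for each map cell.
.nccMap <- function(img, tpl) {
  tr <- nrow(tpl)
  tc <- ncol(tpl)
  nR <- nrow(img) - tr + 1L
  nC <- ncol(img) - tc + 1L
  if (nR < 1L || nC < 1L)
    stop("frame is smaller than the template")
  tplZ <- as.vector(tpl) - mean(tpl)
  tplNorm <- sqrt(sum(tplZ * tplZ))
  map <- matrix(0, nR, nC)
  for (j in seq_len(nC)) {
    cols <- j:(j + tc - 1L)
    block <- img[, cols, drop = FALSE]
    for (i in seq_len(nR))
      map[i, j] <- .nccOne(block[i:(i + tr - 1L), ], tplZ, tplNorm)
  }
  map
}

#' Detect cross markers in a frame
#'
#' Scores every placement of the template over the frame by normalized
#' cross-correlation, keeps local maxima scoring at least `minCorr`, and
#' greedily suppresses non-maxima within one template width (Chebyshev
#' distance). Higher correlation wins; exact ties resolve in row-major
#' order.
#'
#' @param frame Numeric matrix (one luminance frame).
#' @param template A [Template] (or plain odd-sized matrix).
#' @param minCorr Minimum correlation for a detection (default 0.7).
#' @return A data frame with columns `x`, `y` (integer center positions,
#'   pixels) and `corr`, sorted by decreasing correlation; zero rows when
#'   nothing scores at least `minCorr`.
#' @export
detectMarkers <- function(frame, template, minCorr = 0.7) {
  tpl <- if (is(template, "Template")) template@patch else template
  map <- .nccMap(frame, tpl)
  hr <- (nrow(tpl) - 1L) %/% 2L
  hc <- (ncol(tpl) - 1L) %/% 2L
  cand <- which(map >= minCorr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x = integer(), y = integer(), corr = numeric()))
  corr <- map[cand]
  ord <- order(-corr, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  corr <- corr[ord]
  keep <- logical(length(corr))
  width <- max(nrow(tpl), ncol(tpl))
  for (i in seq_along(corr)) {
    if (any(keep)) {
      sel <- which(keep)
      if (any(pmax(abs(cand[sel, 1L] - cand[i, 1L]),
                   abs(cand[sel, 2L] - cand[i, 2L])) < width))
        next
    }
    keep[i] <- TRUE
  }
  data.frame(x = as.integer(cand[keep, 2L] + hc),
             y = as.integer(cand[keep, 1L] + hr),
             corr = corr[keep])
}

#' Refine a correlation peak to sub-pixel precision
#'
#' Least-squares fit of a 2D quadratic (paraboloid with cross term) to the
#' 3 x 3 correlation neighborhood of an integer peak; returns the stationary
#' point of the fit. Offsets beyond one pixel per axis are clipped to
#' +/- 0.5 px with a warning; a singular or non-concave fit falls back to
#' the integer peak with attribute `refined = FALSE`.
#'
#' @param corrSurface Numeric matrix of correlation values.
#' @param peak Integer `(x, y)` position of the peak on `corrSurface`
#'   (column, row); must not lie on the surface border.
#' @return Numeric `(x, y)` continuous peak position, with attribute
#'   `refined` indicating whether the quadratic fit was used.
#' @export
refineSubpixel <- function(corrSurface, peak) {
  px <- peak[1L]
  py <- peak[2L]
  if (px <= 1L || px >= ncol(corrSurface) || py <= 1L ||
      py >= nrow(corrSurface))
    stop("peak must not lie on the border of the correlation surface")
  z <- corrSurface[(py - 1L):(py + 1L), (px - 1L):(px + 1L)]
  co <- .quadFit3x3 %*% as.vector(z)   # a, bu, cv, du^2, euv, gv^2
  h11 <- 2 * co[4L]
  h22 <- 2 * co[6L]
  h12 <- co[5L]
  det <- h11 * h22 - h12^2
  if (!is.finite(det) || det <= 1e-12 || h11 >= 0) {
    out <- c(x = as.numeric(px), y = as.numeric(py))
    attr(out, "refined") <- FALSE
    return(out)
  }
  du <- (-co[2L] * h22 + co[3L] * h12) / det
  dv <- (-co[3L] * h11 + co[2L] * h12) / det
  if (abs(du) > 1 || abs(dv) > 1) {
    warning("sub-pixel offset beyond 1 px; clipping to +/- 0.5 px")
    du <- sign(du) * min(abs(du), 0.5)
    dv <- sign(dv) * min(abs(dv), 0.5)
  }
  out <- c(x = px + du, y = py + dv)
  attr(out, "refined") <- TRUE
  out
}

## Pseudo-inverse mapping the 9 values of a 3x3 neighborhood (column-major,
## offsets u = col - 2, v = row - 2) to quadratic coefficients
## (a, b u, c v, d u^2, e uv, g v^2).
.quadFit3x3 <- local({
  u <- rep(-1:1, each = 3)   # column offset per column-major cell
  v <- rep(-1:1, times = 3)  # row offset
  X <- cbind(1, u, v, u^2, u * v, v^2)
  solve(crossprod(X), t(X))
})

#' Track markers through a clip
#'
#' For each marker, every frame is matched by normalized cross-correlation
#' within a window of `searchRadiusPx` around the position in the previous
#' frame, and the integer peak is refined with [refineSubpixel()]. Tracking
#' is deterministic; per-frame peak correlations are kept as quality.
#'
#' Frames and template are pre-smoothed with a small binomial kernel before
#' correlation (matched filtering on both sides, so the peak location is
#' unchanged); this widens the correlation peak enough for the 3 x 3
#' paraboloid fit to be unbiased to well below 0.01 px.
#'
#' @param clip A [FrameStack] (typically motion-amplified).
#' @param initPositions Numeric matrix with columns `x`, `y`: approximate
#'   marker centers in the first frame (one row per marker); or a data frame
#'   as returned by [detectMarkers()].
#' @param template A [Template] (or list of templates, one per marker).
#' @param searchRadiusPx Integer search radius around the previous position.
#' @param qualityFloor Minimum acceptable peak correlation; if more than 5%
#'   of a marker's frames fall below it, tracking aborts with an error
#'   naming the marker and frame range.
#' @param markerIds Character ids for the output tracks.
#' @return A list of [Track] objects, one per marker.
#' @examples
#' \donttest{
#' cfg <- SceneConfig(widthPx = 48, heightPx = 48, fps = 200, durationS = 0.25,
#'                    noiseSigma = 0,
#'                    markers = list(MarkerSpec(centerPx = c(24, 24))))
#' sim <- simulateClip(cfg)
#' tpl <- makeTemplate(cfg@markers[[1]], cfg@pixelPitchMm)
#' tr <- trackClip(sim$clip, cbind(x = 24, y = 24), tpl)[[1]]
#' head(positions(tr))
#' }
#' @export
trackClip <- function(clip, initPositions, template, searchRadiusPx = 4,
                      qualityFloor = 0.3, markerIds = NULL) {
  stopifnot(is(clip, "FrameStack"))
  if (is.data.frame(initPositions))
    initPositions <- cbind(x = initPositions$x, y = initPositions$y)
  initPositions <- matrix(as.numeric(initPositions),
                          ncol = 2L,
                          dimnames = list(NULL, c("x", "y")))
  nM <- nrow(initPositions)
  tpls <- if (is.list(template) && !is(template, "Template")) template
          else rep(list(template), nM)
  if (is.null(markerIds))
    markerIds <- paste0("m", seq_len(nM))
  a <- .blurStack(clip@frames)
  d <- dim(a)
  nT <- d[3]
  r <- as.integer(searchRadiusPx)

  tracks <- vector("list", nM)
  for (m in seq_len(nM)) {
    tpl <- tpls[[m]]
    tpl <- if (is(tpl, "Template")) tpl@patch else tpl
    tpl <- .blurStack(tpl)[, , 1L]
    tr <- nrow(tpl)
    tc <- ncol(tpl)
    hr <- (tr - 1L) %/% 2L
    hc <- (tc - 1L) %/% 2L
    tplZ <- as.vector(tpl) - mean(tpl)
    tplNorm <- sqrt(sum(tplZ * tplZ))

    pos <- matrix(NA_real_, nT, 2L)
    qual <- numeric(nT)
    prev <- initPositions[m, ]
    for (k in seq_len(nT)) {
      cx <- as.integer(round(prev[1L]))
      cy <- as.integer(round(prev[2L]))
      ## region covering template placements shifted by -(r+1) .. +(r+1)
      rows <- (cy - hr - r - 1L):(cy + hr + r + 1L)
      cols <- (cx - hc - r - 1L):(cx + hc + r + 1L)
      if (rows[1L] < 1L || cols[1L] < 1L || rows[length(rows)] > d[1] ||
          cols[length(cols)] > d[2])
        stop(sprintf(
          "marker '%s' too close to the frame border at frame %d",
          markerIds[m], k))
      region <- a[rows, cols, k]
      map <- matrix(-Inf, 2L * r + 3L, 2L * r + 3L)
      for (jj in seq_len(2L * r + 3L))
        for (ii in seq_len(2L * r + 3L))
          map[ii, jj] <- .nccOne(
            region[ii:(ii + tr - 1L), jj:(jj + tc - 1L)], tplZ, tplNorm)
      ## peak restricted to +/- r (inner part), leaving a ring for the fit
      inner <- map[2L:(2L * r + 2L), 2L:(2L * r + 2L)]
      best <- which(inner == max(inner), arr.ind = TRUE)[1L, ]
      pi <- best[1L] + 1L
      pj <- best[2L] + 1L
      ref <- refineSubpixel(map, c(pj, pi))
      pos[k, ] <- c(cx + (ref[1L] - (r + 2L)), cy + (ref[2L] - (r + 2L)))
      qual[k] <- map[pi, pj]
      prev <- pos[k, ]
    }
    bad <- which(qual < qualityFloor)
    if (length(bad) > 0.05 * nT)
      stop(sprintf(
        "tracking quality below %.2f for %d/%d frames of marker '%s' (frames %d-%d)",
        qualityFloor, length(bad), nT, markerIds[m], min(bad), max(bad)))
    tracks[[m]] <- Track(markerIds[m], pos, qual, clip@fps)
  }
  tracks
}

#' Calibrate pixel pitch from a marker of known size
#'
#' Divides the known physical extent of a marker by its measured extent in
#' pixels, per axis, and propagates a +/- 0.5 px extent-measurement error to
#' first order (`uncertainty = physical / measured^2 * 0.5`).
#'
#' @param physicalExtentMm Numeric `(x, y)` physical extents in mm.
#' @param measuredExtentPx Numeric `(x, y)` measured extents in pixels.
#' @param extentErrorPx Assumed extent measurement error in pixels
#'   (default 0.5).
#' @return A [Calibration].
#' @examples
#' calibrate(c(10, 10), c(20, 20))   # 0.5 mm/px, +/- 0.0125
#' @export
calibrate <- function(physicalExtentMm, measuredExtentPx,
                      extentErrorPx = 0.5) {
  if (any(physicalExtentMm <= 0) || any(measuredExtentPx <= 0))
    stop("physical and measured extents must be positive")
  physicalExtentMm <- rep_len(as.numeric(physicalExtentMm), 2L)
  measuredExtentPx <- rep_len(as.numeric(measuredExtentPx), 2L)
  mm <- physicalExtentMm / measuredExtentPx
  un <- physicalExtentMm / measuredExtentPx^2 * extentErrorPx
  Calibration(mm[1L], mm[2L], un[1L], un[2L])
}
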